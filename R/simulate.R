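#' Define an indel species
#'
#' An indel species is keyed by its signed net length (insertions positive),
#' its position relative to the cut bond, and its inserted bases (if any).
#' For deletions, `position` is the offset of the first deleted base relative
#' to the cut bond (0 = the first base 3' of the bond); for insertions it is
#' the bond at which the bases are inserted.
#'
#' @param net_length Signed net length (nonzero integer).
#' @param position Position relative to the cut bond (default 0).
#' @param inserted Inserted bases (required iff `net_length > 0`).
#' @param polq_dependent Ground-truth flag used by the POLQ-arm simulator.
#' @return An `indel_species` with a canonical `signature` string, e.g.
#'   `"-1@0"` or `"+2@0:CA"`.
#' @export
indel_species <- function(net_length, position = 0L, inserted = "",
                          polq_dependent = FALSE) {
  net_length <- as.integer(net_length)
  if (net_length == 0L) stop("net length must be a nonzero integer")
  if (net_length > 0L && nchar(inserted) != net_length) {
    stop("inserted bases must have length equal to the net insertion length")
  }
  if (net_length < 0L && nchar(inserted) > 0L) {
    stop("a pure deletion species carries no inserted bases")
  }
  sig <- species_signature(net_length, position, inserted)
  structure(list(net_length = net_length, position = as.integer(position),
                 inserted = inserted, polq_dependent = polq_dependent,
                 signature = sig),
            class = "indel_species")
}

species_signature <- function(net_length, position, inserted = "") {
  base <- sprintf("%+d@%d", net_length, position)
  if (nchar(inserted) > 0L) paste0(base, ":", inserted) else base
}

#' Define a ground-truth outcome mixture
#'
#' @param proportions Named numeric vector of class proportions over
#'   `WT`, `HDR`, `HBD_FULL`, `HBD_PARTIAL_5P`, `HBD_PARTIAL_3P`,
#'   `CUTSITE_MISMATCH` and/or indel-species signatures. Must be
#'   nonnegative and sum to 1.
#' @param species List of [indel_species()] objects for every species
#'   signature named in `proportions`.
#' @param error_rate Per-base substitution sequencing-error rate.
#' @return A `truth_mixture`.
#' @export
truth_mixture <- function(proportions, species = list(), error_rate = 0) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)))
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  base_classes <- c("WT", "HDR", "HBD_FULL", "HBD_PARTIAL_5P",
                    "HBD_PARTIAL_3P", "CUTSITE_MISMATCH")
  sigs <- vapply(species, function(s) s$signature, character(1))
  unknown <- setdiff(names(proportions), c(base_classes, sigs))
  if (length(unknown) > 0L) {
    stop("no species definition for mixture class(es): ",
         paste(unknown, collapse = ", "))
  }
  structure(list(proportions = proportions,
                 species = setNames(species, sigs),
                 error_rate = error_rate),
            class = "truth_mixture")
}

# Build the exact (noise-free) template sequence of a mixture class.
class_template <- function(class, panel) {
  s <- panel$sequences
  if (class %in% names(s)) return(unname(s[[class]]))
  if (class == "CUTSITE_MISMATCH") {
    snp <- cut_proximal_snp(panel)
    wt <- strsplit(s[["WT"]], "")[[1]]
    wt[snp$offset + 1L] <- snp$alt
    return(paste(wt, collapse = ""))
  }
  stop("unknown base class: ", class)
}

apply_species <- function(panel, sp) {
  wt <- strsplit(panel$sequences[["WT"]], "")[[1]]
  pos <- panel$cut + sp$position
  if (sp$net_length < 0L) {
    del <- (pos + 1L):(pos - sp$net_length)
    if (any(del < 1L) || any(del > length(wt))) {
      stop("indel species extends outside the amplicon")
    }
    wt <- wt[-del]
  } else {
    if (pos < 0L || pos > length(wt)) {
      stop("indel species extends outside the amplicon")
    }
    wt <- append(wt, strsplit(sp$inserted, "")[[1]], after = pos)
  }
  paste(wt, collapse = "")
}

# Vectorised substitution noise: each base flips to one of the three other
# bases independently with probability error_rate.
add_substitution_noise <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  vapply(reads, function(r) {
    v <- strsplit(r, "")[[1]]
    hit <- which(runif(length(v)) < error_rate)
    if (length(hit) > 0L) {
      v[hit] <- vapply(v[hit],
                       function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon reads from a known outcome mixture
#'
#' Each read is drawn from a mixture class by multinomial sampling, built
#' from that class's template (WT/HDR/conversion amplicon, cut-site
#' mismatch, or WT with the species indel applied), then subjected to
#' independent per-base substitution noise. Reads are single full-length
#' amplicon spans.
#'
#' @param panel An [make_panel()] panel.
#' @param mixture A [truth_mixture()].
#' @param n_reads Number of reads (>= 1).
#' @param seed Integer seed.
#' @return List with `reads` (character vector named `read_1`...) and
#'   `truth` (data frame `read_id`, `class`).
#' @export
simulate_reads <- function(panel, mixture, n_reads, seed = 1L) {
  stopifnot(inherits(panel, "amplicon_panel"),
            inherits(mixture, "truth_mixture"), n_reads >= 1L)
  set.seed(seed)
  classes <- names(mixture$proportions)
  templates <- vapply(classes, function(cl) {
    if (cl %in% names(mixture$species)) {
      apply_species(panel, mixture$species[[cl]])
    } else {
      class_template(cl, panel)
    }
  }, character(1))
  idx <- sample.int(length(classes), n_reads, replace = TRUE,
                    prob = mixture$proportions)
  reads <- add_substitution_noise(unname(templates[idx]),
                                  mixture$error_rate)
  ids <- paste0("read_", seq_len(n_reads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, class = classes[idx],
                          stringsAsFactors = FALSE))
}

#' Write / read FASTQ with constant qualities
#'
#' Qualities are constant `"I"` (Q40); no trimming is performed anywhere in
#' the pipeline.
#'
#' @param reads Named character vector of reads.
#' @param path FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% paste0("read_", seq_along(reads))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Define ground truth for a sorted-pool variant screen
#'
#' @param whitelist A whitelist data frame from [build_whitelist()].
#' @param enrichment Named numeric vector of per-variant enrichment factors
#'   (ratio of HDR-positive to HDR-negative relative frequency); default all 1.
#' @param baseline Named baseline HDR-negative frequencies (default uniform);
#'   must sum to 1.
#' @param n_reps Number of replicates.
#' @param depth Sequencing depth (reads per sample).
#' @return A `screen_truth`.
#' @export
screen_truth <- function(whitelist, enrichment = NULL, baseline = NULL,
                         n_reps = 3L, depth = 1e6) {
  ids <- unique(whitelist$variant_id)
  enrichment <- enrichment %||% setNames(rep(1, length(ids)), ids)
  baseline <- baseline %||% setNames(rep(1 / length(ids), length(ids)), ids)
  if (!setequal(names(enrichment), ids) || !setequal(names(baseline), ids)) {
    stop("enrichment and baseline must be defined for every whitelist id")
  }
  if (any(enrichment <= 0)) stop("enrichment factors must be > 0")
  if (abs(sum(baseline) - 1) > 1e-9) stop("baseline frequencies must sum to 1")
  structure(list(whitelist = whitelist,
                 enrichment = enrichment[ids], baseline = baseline[ids],
                 n_reps = as.integer(n_reps), depth = depth),
            class = "screen_truth")
}

#' Simulate paired sorted-pool count tables
#'
#' HDR-negative counts are multinomial at the baseline frequencies;
#' HDR-positive counts are multinomial at the baseline scaled by the
#' enrichment factors and renormalised.
#'
#' @param truth A [screen_truth()].
#' @param seed Integer seed.
#' @return List of replicates; each has `plus` and `minus`
#'   `variant_count_table` objects.
#' @export
simulate_screen_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "screen_truth"))
  if (truth$depth <= 0) stop("depth must be > 0")
  set.seed(seed)
  ids <- names(truth$baseline)
  p_minus <- truth$baseline
  p_plus <- truth$baseline * truth$enrichment
  p_plus <- p_plus / sum(p_plus)
  lapply(seq_len(truth$n_reps), function(r) {
    minus <- drop(rmultinom(1L, truth$depth, p_minus))
    plus <- drop(rmultinom(1L, truth$depth, p_plus))
    list(plus = variant_count_table(setNames(plus, ids),
                                    sample = sprintf("rep%d_plus", r),
                                    replicate = r, pool = "GFP_PLUS"),
         minus = variant_count_table(setNames(minus, ids),
                                     sample = sprintf("rep%d_minus", r),
                                     replicate = r, pool = "GFP_MINUS"))
  })
}

#' Simulate paired POLQ-knockdown vs control outcome tables
#'
#' The knockdown arm scales each POLQ-dependent species' proportion by its
#' multiplier and renormalises; counts are multinomial per replicate.
#' Freed probability mass is redistributed proportionally (renormalisation),
#' as expected when one repair pathway is suppressed.
#'
#' @param mixture A [truth_mixture()] describing the control arm.
#' @param knockdown_multiplier Named numeric vector (by species signature)
#'   of multiplicative reductions in `(0, 1]` for POLQ-dependent species;
#'   species not named keep multiplier 1. A multiplier of 0 removes the
#'   species from the knockdown arm.
#' @param n_reps Replicates per arm (a warning is recorded if < 2, since
#'   the downstream test is then undefined).
#' @param depth Alleles sampled per replicate.
#' @param seed Integer seed.
#' @return Data frame with columns `species`/`class`, `arm`
#'   (`knockdown`/`control`), `replicate`, `count`, `fraction`.
#' @export
simulate_polq_arms <- function(mixture, knockdown_multiplier = NULL,
                               n_reps = 3L, depth = 1e5, seed = 1L) {
  stopifnot(inherits(mixture, "truth_mixture"))
  if (n_reps < 2L) {
    warning("fewer than 2 replicates per arm: the MMEJ test is undefined")
  }
  set.seed(seed)
  p_ctrl <- mixture$proportions
  mult <- setNames(rep(1, length(p_ctrl)), names(p_ctrl))
  if (!is.null(knockdown_multiplier)) {
    unknown <- setdiff(names(knockdown_multiplier), names(p_ctrl))
    if (length(unknown) > 0L) {
      stop("multiplier given for unknown class: ",
           paste(unknown, collapse = ", "))
    }
    if (any(knockdown_multiplier < 0 | knockdown_multiplier > 1)) {
      stop("multipliers must be in [0, 1]")
    }
    mult[names(knockdown_multiplier)] <- knockdown_multiplier
  }
  p_kd <- p_ctrl * mult
  p_kd <- p_kd / sum(p_kd)
  one_arm <- function(p, arm) {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      cnt <- drop(rmultinom(1L, depth, p))
      data.frame(class = names(p_ctrl), arm = arm, replicate = r,
                 count = cnt, fraction = cnt / depth,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  rbind(one_arm(p_kd, "knockdown"), one_arm(p_ctrl, "control"))
}

#' Simulate CFU colonies with known genotypes
#'
#' Diploid colonies emit reads ~50/50 from their two alleles; a
#' `contamination_rate` fraction emit from three alleles (not a single
#' clone). Depth is drawn per colony from `depth_distribution` and may fall
#' below the 2000-read genotyping threshold; such colonies are flagged
#' `expected_filtered` in the truth table.
#'
#' @param n_colonies Number of colonies.
#' @param genotype_distribution List with `pairs` (list of 2-long character
#'   vectors of allele names: `"WT"`, `"HDR"`, or species signatures) and
#'   `probs` (matching probabilities).
#' @param depth_distribution Integer vector to sample depths from, or a
#'   `function(n)` returning depths.
#' @param contamination_rate Fraction of colonies receiving a third allele.
#' @param panel Amplicon panel used to build allele template sequences.
#' @param species Named list of [indel_species()] for any species allele
#'   names used.
#' @param error_rate Per-base substitution noise on emitted reads.
#' @param seed Integer seed.
#' @return List with `reads` (list of named read vectors per colony) and
#'   `truth` (data frame: colony_id, allele1/allele2 (the observable allele
#'   pair), allele3 (contaminating allele or NA), depth, contaminated,
#'   expected_filtered, filter_reason). A contaminated homozygous colony
#'   presents only two distinct alleles; its observable genotype is that
#'   mixture and it is not expected to be caught by the allele-count filter.
#' @export
simulate_colonies <- function(n_colonies, genotype_distribution,
                              depth_distribution = 3000:6000,
                              contamination_rate = 0, panel,
                              species = list(), error_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "amplicon_panel"))
  pairs <- genotype_distribution$pairs
  probs <- genotype_distribution$probs
  if (length(pairs) == 0L) stop("empty genotype distribution")
  stopifnot(length(pairs) == length(probs))
  set.seed(seed)

  allele_template <- function(name) {
    if (name %in% names(species)) apply_species(panel, species[[name]])
    else class_template(name, panel)
  }
  all_alleles <- unique(c(unlist(pairs), names(species)))
  templates <- vapply(all_alleles, allele_template, character(1))

  draw_depth <- if (is.function(depth_distribution)) {
    function() depth_distribution(1L)
  } else {
    function() depth_distribution[sample.int(length(depth_distribution), 1L)]
  }

  truth <- vector("list", n_colonies)
  reads <- vector("list", n_colonies)
  for (i in seq_len(n_colonies)) {
    pair <- pairs[[sample.int(length(pairs), 1L, prob = probs)]]
    alleles <- pair
    contaminated <- runif(1) < contamination_rate
    if (contaminated) {
      pool <- setdiff(all_alleles, pair)
      extra <- pool[sample.int(length(pool), 1L)]
      alleles <- c(pair, extra)
    }
    depth <- draw_depth()
    src <- sample(alleles, depth, replace = TRUE)
    colony_reads <- add_substitution_noise(unname(templates[src]), error_rate)
    names(colony_reads) <- paste0("col", i, "_read_", seq_len(depth))
    reads[[i]] <- colony_reads
    # a third distinct allele is only detectable (and hence expected to be
    # filtered) when the colony's own pair is heterozygous; a contaminated
    # homozygous colony presents two distinct alleles, and its observable
    # genotype is recorded as that mixture
    n_distinct <- length(unique(alleles))
    reason <- if (depth < 2000L) "low_depth"
              else if (n_distinct > 2L) "too_many_alleles"
              else NA_character_
    observable <- if (contaminated && n_distinct == 2L) {
      unique(alleles)
    } else pair
    truth[[i]] <- data.frame(
      colony_id = paste0("colony_", i),
      allele1 = observable[1], allele2 = observable[2],
      allele3 = if (contaminated) alleles[3] else NA_character_,
      depth = depth,
      contaminated = contaminated,
      expected_filtered = !is.na(reason),
      filter_reason = reason,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  names(reads) <- truth$colony_id
  list(reads = reads, truth = truth)
}
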