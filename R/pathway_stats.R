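#' Paired knockdown/control design for MMEJ partitioning
#'
#' @param fractions Data frame with columns `class` (or `species`), `arm`
#'   (`"knockdown"`/`"control"`), `replicate`, `fraction` - e.g. the output
#'   of [simulate_polq_arms()] or stacked allele-fraction tables.
#' @return A `paired_design` data frame restricted to indel species rows
#'   (class names carrying an indel signature) unless `species_only=FALSE`.
#' @param species_only Keep only rows whose class parses as an indel
#'   species signature.
#' @export
paired_design <- function(fractions, species_only = TRUE) {
  if ("species" %in% names(fractions) && !"class" %in% names(fractions)) {
    names(fractions)[names(fractions) == "species"] <- "class"
  }
  need <- c("class", "arm", "replicate", "fraction")
  stopifnot(all(need %in% names(fractions)))
  if (!all(fractions$arm %in% c("knockdown", "control"))) {
    stop("arm must be 'knockdown' or 'control'")
  }
  if (any(fractions$fraction < 0 | fractions$fraction > 1)) {
    stop("fractions must be in [0, 1]")
  }
  if (species_only) {
    fractions <- fractions[grepl("^[+-]?\\d+@", fractions$class), ,
                           drop = FALSE]
  }
  class(fractions) <- c("paired_design", "data.frame")
  fractions
}

# One-sided Welch p-value for "fraction lower under knockdown".
# Constant-data degenerate cases are resolved by symmetry: equal arms give
# p = 0.5; unequal constant arms give 0 or 1 by the direction of the shift.
welch_one_sided <- function(control, knockdown) {
  if (length(unique(c(control, knockdown))) == 1L) return(0.5)
  p <- tryCatch(
    t.test(control, knockdown, alternative = "greater",
           var.equal = FALSE)$p.value,
    error = function(e) {
      if (mean(control) > mean(knockdown)) 0 else 1
    })
  p
}

#' Collapse a paired design to net indel length
#'
#' Fallback matching mode: species are often reported by signed net length
#' only, so exact signatures (which encode position and inserted bases) can
#' be collapsed to length classes before testing. Fractions of species with
#' the same net length are summed within each arm and replicate.
#'
#' @param design A [paired_design()].
#' @return A `paired_design` whose class labels are net lengths
#'   (`"-1"`, `"+2"`, ...).
#' @export
collapse_species_by_length <- function(design) {
  stopifnot(all(grepl("^[+-]?\\d+@", design$class)))
  len <- sub("@.*", "", design$class)
  agg <- stats::aggregate(fraction ~ len + arm + replicate, data =
                            cbind(design, len = len), FUN = sum)
  names(agg)[names(agg) == "len"] <- "class"
  agg <- agg[, c("class", "arm", "replicate", "fraction")]
  class(agg) <- c("paired_design", "data.frame")
  agg
}

#' Partition indel species into MMEJ vs NHEJ via POLQ knockdown
#'
#' For each indel species with at least `min_control_fraction` mean
#' abundance in the control arm and >= 2 replicates per arm, a one-sided
#' Welch t-test asks whether the species' allele fraction is lower under
#' POLQ knockdown. p-values are Benjamini-Hochberg adjusted across all
#' tested species; species with q-value below `alpha` are labelled
#' POLQ-dependent (`MMEJ`), all others (including untested species)
#' default to `NHEJ`.
#'
#' @param design A [paired_design()].
#' @param alpha FDR threshold (default 0.1).
#' @param min_control_fraction Minimum mean control-arm fraction for a
#'   species to be tested (default 0.001 of alleles).
#' @return A `species_calls` data frame: `species`, `p`, `q`, `label`,
#'   `tested`, `reason`.
#' @export
classify_mmej <- function(design, alpha = 0.1, min_control_fraction = 0.001) {
  stopifnot(inherits(design, "paired_design") || is.data.frame(design))
  sp <- unique(design$class)
  res <- lapply(sp, function(s) {
    d <- design[design$class == s, , drop = FALSE]
    ctrl <- d$fraction[d$arm == "control"]
    kd <- d$fraction[d$arm == "knockdown"]
    if (length(ctrl) < 2L || length(kd) < 2L) {
      return(data.frame(species = s, p = NA_real_, tested = FALSE,
                        reason = "fewer than 2 replicates",
                        stringsAsFactors = FALSE))
    }
    if (mean(ctrl) < min_control_fraction) {
      return(data.frame(species = s, p = NA_real_, tested = FALSE,
                        reason = "below minimum control fraction",
                        stringsAsFactors = FALSE))
    }
    data.frame(species = s, p = welch_one_sided(ctrl, kd), tested = TRUE,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  if (any(res$tested)) {
    res$q[res$tested] <- p.adjust(res$p[res$tested], method = "BH")
  }
  res$label <- ifelse(res$tested & !is.na(res$q) & res$q < alpha,
                      "MMEJ", "NHEJ")
  res <- res[, c("species", "p", "q", "label", "tested", "reason")]
  class(res) <- c("species_calls", "data.frame")
  res
}

#' Summarise editing outcomes
#'
#' All-allele percentages (over non-discarded reads) of the five outcome
#' classes: `%WT` (unedited), `%HDR` (intended repair), `%HBD` (full +
#' partial gene conversion + cut-site mismatch), `%MMEJ` (indel species
#' labelled POLQ-dependent) and `%NHEJ` (all remaining indel species).
#' The edited-allele view expresses each edit as a percentage of edited
#' alleles, `x / (100 - %WT) * 100`; it is unavailable when `%WT = 100`.
#'
#' @param tally An [tally_reads()] outcome tally.
#' @param calls Optional [classify_mmej()] species calls; species without a
#'   call default to NHEJ.
#' @return An `editing_summary`: list with `all_alleles` (named percentages
#'   summing to 100) and `edited_alleles` (named percentages or `NA`).
#' @export
summarize_outcomes <- function(tally, calls = NULL) {
  stopifnot(inherits(tally, "outcome_tally"))
  cl <- tally$classes
  denom <- sum(cl) - cl[["DISCARDED"]]
  if (denom <= 0) stop("no classified reads")
  mmej_sigs <- if (!is.null(calls)) calls$species[calls$label == "MMEJ"]
               else character(0)
  sp <- tally$species
  mmej <- sum(sp$count[sp$signature %in% mmej_sigs])
  nhej <- sum(sp$count[!sp$signature %in% mmej_sigs])
  # INDEL reads with no WT-referenced species signature count as NHEJ
  nhej <- nhej + (cl[["INDEL"]] - sum(sp$count))
  hbd <- cl[["HBD_FULL"]] + cl[["HBD_PARTIAL_5P"]] +
    cl[["HBD_PARTIAL_3P"]] + cl[["CUTSITE_MISMATCH"]]
  pct <- 100 * c(WT = cl[["WT"]], HDR = cl[["HDR"]], HBD = unname(hbd),
                 MMEJ = mmej, NHEJ = nhej) / denom
  edited <- if (pct[["WT"]] >= 100 - 1e-9) {
    setNames(rep(NA_real_, 4L), c("HDR", "HBD", "MMEJ", "NHEJ"))
  } else {
    100 * pct[c("HDR", "HBD", "MMEJ", "NHEJ")] / (100 - pct[["WT"]])
  }
  structure(list(all_alleles = pct, edited_alleles = edited,
                 species = sp, mmej_signatures = mmej_sigs,
                 n_classified = unname(denom)),
            class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("Editing summary (% of all alleles):\n")
  print(round(x$all_alleles, 2))
  cat("As % of edited alleles:\n")
  print(round(x$edited_alleles, 2))
  invisible(x)
}

species_length_fractions <- function(summary, classes) {
  sp <- summary$species
  nhej <- sp[!sp$signature %in% summary$mmej_signatures, , drop = FALSE]
  denom <- summary$n_classified
  in_cls <- nhej$net_length %in% classes
  c(listed = sum(nhej$count[in_cls]) / denom,
    other = sum(nhej$count[!in_cls]) / denom)
}

#' Percent inhibition of NHEJ indels by length class
#'
#' Compares the all-allele fraction of NHEJ-derived indels (MMEJ species
#' excluded from both sides) between a treated and a control sample, split
#' into the listed length classes (default net lengths -1, -2, +2) and all
#' other lengths:
#' `inhibition% = 100 * (1 - fraction_treated / fraction_control)`.
#' Enrichment under treatment reports as negative inhibition; a zero
#' control fraction yields `NA`.
#'
#' @param treated,control [summarize_outcomes()] summaries from the same
#'   panel and window, with MMEJ labels applied.
#' @param classes Net lengths of the listed class (default `c(-1, -2, 2)`).
#' @return Data frame `length_class`, `fraction_treated`,
#'   `fraction_control`, `inhibition_pct`.
#' @export
inhibition_by_length <- function(treated, control, classes = c(-1L, -2L, 2L)) {
  stopifnot(inherits(treated, "editing_summary"),
            inherits(control, "editing_summary"))
  ft <- species_length_fractions(treated, classes)
  fc <- species_length_fractions(control, classes)
  inhibition <- ifelse(fc > 0, 100 * (1 - ft / fc), NA_real_)
  data.frame(
    length_class = c(paste0("[", paste(sprintf("%+d", classes),
                                       collapse = ", "), "]"),
                     "other lengths"),
    fraction_treated = unname(ft), fraction_control = unname(fc),
    inhibition_pct = unname(inhibition),
    row.names = NULL, stringsAsFactors = FALSE)
}
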