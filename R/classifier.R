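#' Quantification window around the cut bond
#'
#' Indels are counted as editing events only when they overlap this window.
#' A half-width of `w` covers the `2w` reference bases centred on the cut
#' bond, i.e. offsets `[cut - w, cut + w - 1]`; an insertion overlaps when
#' its anchor lies strictly between `cut - w` and `cut + w`.
#'
#' @param panel An [make_panel()] panel (supplies the cut bond offset).
#' @param half_width Window half-width in nt (default 1, the narrowest
#'   conventional window).
#' @return A `quant_window`: list with `cut`, `half_width`, `bases`.
#' @export
quant_window <- function(panel, half_width = 1L) {
  stopifnot(inherits(panel, "amplicon_panel"), half_width >= 1L)
  w <- as.integer(half_width)
  bases <- (panel$cut - w):(panel$cut + w - 1L)
  if (any(bases < 0L) || any(bases >= panel$length)) {
    stop("quantification window extends outside the amplicon")
  }
  structure(list(cut = panel$cut, half_width = w, bases = bases),
            class = "quant_window")
}

# Overlap is assessed against the bond interval [cut - w, cut + w]:
# a deletion [s, e) spans bonds s..e and overlaps when s <= cut + w and
# e >= cut - w; an insertion overlaps when its anchor bond lies inside the
# interval (inclusive). The inclusive ends matter because leftmost gap
# placement can shift an indel by one position along a homopolymer run.
event_overlaps_window <- function(events, window) {
  if (nrow(events) == 0L) return(logical(0))
  c0 <- window$cut - window$half_width
  c1 <- window$cut + window$half_width
  vapply(seq_len(nrow(events)), function(k) {
    type <- events$type[k]
    s <- events$ref_start[k]
    e <- events$ref_end[k]
    if (type == "deletion") s <= c1 && e >= c0
    else if (type == "insertion") s >= c0 && s <= c1
    else s %in% window$bases  # substitution at a window base
  }, logical(1))
}

# Species signature from the window-overlapping indel events of a
# WT-referenced alignment: summed net length, leftmost offset (relative to
# the cut bond), concatenated inserted bases.
species_from_alignment <- function(alignment, window) {
  ev <- alignment$events
  indel <- ev$type %in% c("deletion", "insertion")
  keep <- indel & event_overlaps_window(ev, window)
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) return(NULL)
  net <- sum(ifelse(ev$type == "insertion", nchar(ev$bases),
                    -(ev$ref_end - ev$ref_start)))
  leftmost <- min(ev$ref_start) - window$cut
  inserted <- paste(ev$bases[ev$type == "insertion"], collapse = "")
  list(net_length = as.integer(net),
       position = as.integer(leftmost),
       inserted = inserted,
       signature = if (net == 0L) {
         # net-zero combinations keep an explicit signature
         sprintf("0@%d%s", leftmost,
                 if (nchar(inserted)) paste0(":", inserted) else "")
       } else species_signature(net, leftmost, inserted))
}

AMPLICON_PRECEDENCE <- c("HDR", "WT", "HBD_FULL", "HBD_PARTIAL_5P",
                         "HBD_PARTIAL_3P")

#' Classify one amplicon read
#'
#' The read is globally aligned against all five panel amplicons and
#' assigned to the best-scoring one (score ties break by fixed precedence
#' HDR > WT > full conversion > 5' partial > 3' partial). Classification
#' rules, in order: reads below the identity floor are `DISCARDED`; reads
#' with any indel overlapping the quantification window are `INDEL`, with
#' the species signature taken from the WT-referenced alignment; otherwise
#' the class is the assigned amplicon - except that a WT-assigned read with
#' a substitution at a window base and no indel anywhere is
#' `CUTSITE_MISMATCH` (a minimal gene-conversion tract).
#'
#' @param read DNA string.
#' @param panel An [make_panel()] panel.
#' @param window A [quant_window()].
#' @param params An [align_params()].
#' @param both_orientations Also align the reverse complement and keep the
#'   better orientation (off by default; synthetic reads are oriented).
#' @return List with `class`, `species` (signature or `NA`), `assigned`
#'   (best amplicon name), `score`, `identity`.
#' @export
classify_read <- function(read, panel, window = quant_window(panel),
                          params = align_params(),
                          both_orientations = FALSE) {
  stopifnot(inherits(panel, "amplicon_panel"),
            inherits(window, "quant_window"))
  if (both_orientations) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read)))
    fwd <- classify_read(read, panel, window, params, FALSE)
    rev <- classify_read(rc, panel, window, params, FALSE)
    return(if (rev$score > fwd$score) rev else fwd)
  }
  alns <- lapply(panel$sequences[AMPLICON_PRECEDENCE], function(ref)
    align_global(read, ref, params))
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best <- AMPLICON_PRECEDENCE[which.max(scores)]  # which.max: first = precedence
  aln <- alns[[best]]

  if (aln$identity < params$min_identity) {
    return(list(class = "DISCARDED", species = NA_character_,
                assigned = best, score = aln$score,
                identity = aln$identity))
  }
  ev <- aln$events
  indel <- ev$type %in% c("deletion", "insertion")
  if (any(indel & event_overlaps_window(ev, window))) {
    sp <- species_from_alignment(alns[["WT"]], window)
    sig <- if (is.null(sp)) NA_character_ else sp$signature
    return(list(class = "INDEL", species = sig, assigned = best,
                score = aln$score, identity = aln$identity))
  }
  cls <- best
  if (best == "WT" && !any(indel)) {
    subs_in_window <- ev$type == "substitution" &
      event_overlaps_window(ev, window)
    if (any(subs_in_window)) cls <- "CUTSITE_MISMATCH"
  }
  list(class = cls, species = NA_character_, assigned = best,
       score = aln$score, identity = aln$identity)
}

#' Tally editing outcomes over a read set
#'
#' Classifies every read and aggregates per-class and per-species counts.
#' The aggregated gene-conversion count (`hbd_aggregate`) sums full and
#' partial conversion reads plus cut-site mismatches. Identical reads are
#' classified once and counted by multiplicity.
#'
#' @inheritParams classify_read
#' @param reads Character vector of reads.
#' @return An `outcome_tally`: list with `classes` (named counts, always
#'   reporting all base classes plus `INDEL` and `DISCARDED`), `species`
#'   (data frame `signature`, `net_length`, `count`), `hbd_aggregate`,
#'   `n_reads`.
#' @export
tally_reads <- function(reads, panel, window = quant_window(panel),
                        params = align_params(),
                        both_orientations = FALSE) {
  if (length(reads) == 0L) stop("empty read set")
  uniq <- unique(reads)
  mult <- as.numeric(table(factor(reads, levels = uniq)))
  cls <- character(length(uniq))
  spc <- character(length(uniq))
  for (k in seq_along(uniq)) {
    r <- classify_read(uniq[k], panel, window, params, both_orientations)
    cls[k] <- r$class
    spc[k] <- r$species
  }
  base_classes <- c("WT", "HDR", "HBD_FULL", "HBD_PARTIAL_5P",
                    "HBD_PARTIAL_3P", "CUTSITE_MISMATCH", "INDEL",
                    "DISCARDED")
  classes <- vapply(base_classes, function(b) sum(mult[cls == b]),
                    numeric(1))
  is_sp <- cls == "INDEL" & !is.na(spc)
  species <- if (any(is_sp)) {
    agg <- tapply(mult[is_sp], spc[is_sp], sum)
    data.frame(signature = names(agg),
               net_length = as.integer(sub("@.*", "", names(agg))),
               count = as.numeric(agg),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(signature = character(0), net_length = integer(0),
               count = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(classes = classes, species = species,
                 hbd_aggregate = unname(classes[["HBD_FULL"]] +
                   classes[["HBD_PARTIAL_5P"]] +
                   classes[["HBD_PARTIAL_3P"]] +
                   classes[["CUTSITE_MISMATCH"]]),
                 n_reads = length(reads)),
            class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat("Outcome tally over", x$n_reads, "reads:\n")
  print(x$classes)
  if (nrow(x$species) > 0L) {
    cat("Indel species:\n")
    print(x$species)
  }
  invisible(x)
}
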