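#' Alignment scoring parameters
#'
#' Defaults mirror needle-style scoring commonly used for amplicon indel
#' calling: match +5, mismatch -4, gap open -20, gap extend -2 (a gap of
#' length L scores `gap_open + L * gap_extend`). `min_identity` is the
#' minimum fraction of read bases matching the reference for a read to be
#' classified rather than discarded.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap-opening score (<= gap_extend <= 0).
#' @param gap_extend Per-base gap-extension score.
#' @param min_identity Minimum identity fraction in (0, 1].
#' @return An `align_params` list.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = -20,
                         gap_extend = -2, min_identity = 0.6) {
  stopifnot(match > 0, mismatch < 0)
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("require gap_open <= gap_extend <= 0 (scores, i.e. penalties ",
         "gap_open >= gap_extend >= 0)")
  }
  if (!(min_identity > 0 && min_identity <= 1)) {
    stop("min_identity must be in (0, 1]")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "align_params")
}

check_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(what, " must be a nonempty DNA string")
  }
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains non-nucleotide characters (allowed: A,C,G,T,N)")
  }
  x
}

#' Global affine-gap alignment of a read against a reference
#'
#' Optimal Needleman-Wunsch alignment under [align_params()], with
#' deterministic tie-breaking: substitutions are preferred over gaps, and
#' among equal-scoring gap placements the leftmost is chosen. `N` matches
#' nothing and scores as a mismatch. All coordinates are 0-based; deletions
#' are half-open reference intervals; an insertion is anchored to the
#' reference offset it precedes.
#'
#' @param read,reference DNA strings over `{A,C,G,T,N}`.
#' @param params An [align_params()].
#' @return An `alignment`: list with `score`, `n_match`, `aln_len`,
#'   `identity` (matches / read length), `cigar_ops` and `events`
#'   (data frame `type`, `ref_start`, `ref_end`, `bases`).
#' @export
align_global <- function(read, reference, params = align_params()) {
  check_dna(read, "read")
  check_dna(reference, "reference")
  res <- .nw_affine(read, reference, params$match, params$mismatch,
                    params$gap_open, params$gap_extend)
  structure(list(reference = reference, score = res$score,
                 n_match = res$n_match, aln_len = res$aln_len,
                 identity = res$n_match / nchar(read),
                 cigar_ops = res$cigar_ops, events = res$events),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Global alignment: score", x$score, "| identity",
      sprintf("%.3f", x$identity), "|", nrow(x$events), "event(s)\n")
  invisible(x)
}

#' Reconstruct the read from reference plus alignment events
#'
#' Exact inverse of the alignment event encoding; used to verify that event
#' lists losslessly describe the read.
#'
#' @param alignment An [align_global()] result.
#' @param reference The reference it was aligned to (defaults to the one
#'   stored in the alignment).
#' @return The read sequence implied by `reference` + events.
#' @export
reconstruct_read <- function(alignment, reference = alignment$reference) {
  ref <- strsplit(reference, "")[[1]]
  ev <- alignment$events
  # apply right-to-left so earlier coordinates stay valid; at equal start,
  # apply the deletion before an adjacent insertion
  ord <- order(-ev$ref_start, ev$type == "insertion")
  out <- ref
  for (k in ord) {
    type <- ev$type[k]
    s <- ev$ref_start[k]
    e <- ev$ref_end[k]
    if (type == "substitution") {
      out[s + 1L] <- ev$bases[k]
    } else if (type == "deletion") {
      out <- out[-((s + 1L):e)]
    } else {
      out <- append(out, strsplit(ev$bases[k], "")[[1]], after = s)
    }
  }
  paste(out, collapse = "")
}
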