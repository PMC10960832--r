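#' Variant count table
#'
#' Container for whitelist-matched read counts of one sequenced sample.
#'
#' @param counts Named integer vector (variant id -> read count).
#' @param sample Sample id.
#' @param replicate Replicate id.
#' @param pool `"GFP_PLUS"` or `"GFP_MINUS"`.
#' @param discarded Count of non-whitelist reads.
#' @return A `variant_count_table`.
#' @export
variant_count_table <- function(counts, sample, replicate, pool,
                                discarded = 0L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0), discarded >= 0)
  pool <- match.arg(pool, c("GFP_PLUS", "GFP_MINUS"))
  structure(list(sample = sample, replicate = replicate, pool = pool,
                 counts = counts, total_mapped = sum(counts),
                 discarded = as.numeric(discarded)),
            class = "variant_count_table")
}

#' @export
print.variant_count_table <- function(x, ...) {
  cat("Variant counts:", x$sample, "(", x$pool, ", rep", x$replicate, "):",
      x$total_mapped, "mapped /", x$discarded, "discarded\n")
  invisible(x)
}

#' Count whitelist-matched reads
#'
#' Reads are matched against the whitelist by exact full-sequence identity;
#' anything else is discarded, never fuzzily rescued. Mapped plus discarded
#' always equals the input read count.
#'
#' @param reads Character vector of reads.
#' @param whitelist Whitelist data frame ([build_whitelist()]).
#' @param sample,replicate,pool Sample annotations.
#' @param include_stops Count reads matching stop-codon whitelist entries
#'   in the mapped totals (default). With `FALSE` they are discarded
#'   instead; whether such reads belong in totals is not settled, so both
#'   behaviours are exposed.
#' @return A [variant_count_table()].
#' @export
count_variants <- function(reads, whitelist, sample = "sample",
                           replicate = 1L, pool = "GFP_MINUS",
                           include_stops = TRUE) {
  if (nrow(whitelist) == 0L) stop("whitelist is empty")
  if (!include_stops) {
    whitelist <- whitelist[whitelist$class != "stop", , drop = FALSE]
  }
  ids <- unique(whitelist$variant_id)
  hit <- match(reads, whitelist$dna_sequence)
  counts <- setNames(rep(0, length(ids)), ids)
  if (length(reads) > 0L) {
    tab <- table(factor(whitelist$variant_id[hit[!is.na(hit)]],
                        levels = ids))
    counts <- counts + as.numeric(tab)
    names(counts) <- ids
  }
  variant_count_table(counts, sample = sample, replicate = replicate,
                      pool = pool, discarded = sum(is.na(hit)))
}

#' Quality-control a screen sample
#'
#' Gates: (1) mapped reads must exceed `min_reads`; (2) the pooled
#' internal-control frequency must not deviate from the parent carry-over
#' frequency by more than `max_ic_deviation` (relative difference
#' `|f_ic - f_parent| / f_parent`; the gate is inclusive, deviation equal to
#' the threshold passes); (3) no single variant may exceed `max_skew` of
#' mapped reads (library diversity / minimal skewing).
#'
#' @param table A [variant_count_table()].
#' @param whitelist Whitelist with `class` column identifying `parent` and
#'   `internal_control` entries.
#' @param min_reads Mapped-read gate (default 1e5).
#' @param max_ic_deviation Internal-control deviation gate (default 0.10).
#' @param max_skew Maximum single-variant frequency (default 0.5).
#' @return A `qc_report`: list with `pass`, `reasons`, `mapped`,
#'   `ic_deviation`, `skew`.
#' @export
qc_sample <- function(table, whitelist, min_reads = 1e5,
                      max_ic_deviation = 0.10, max_skew = 0.5) {
  stopifnot(inherits(table, "variant_count_table"))
  reasons <- character(0)
  if (table$total_mapped < min_reads) reasons <- c(reasons, "low depth")

  parent_ids <- whitelist$variant_id[whitelist$class == "parent"]
  ic_ids <- whitelist$variant_id[whitelist$class == "internal_control"]
  f <- table$counts / max(table$total_mapped, 1)
  f_parent <- sum(f[names(f) %in% parent_ids])
  f_ic <- sum(f[names(f) %in% ic_ids])
  if (f_parent == 0) {
    reasons <- c(reasons, "parent absent")
    deviation <- NA_real_
  } else {
    deviation <- abs(f_ic - f_parent) / f_parent
    if (deviation > max_ic_deviation + 1e-12) {
      reasons <- c(reasons, "internal control deviation")
    }
  }
  skew <- if (table$total_mapped > 0) max(f) else 0
  if (skew > max_skew) reasons <- c(reasons, "library skew")

  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 mapped = table$total_mapped, ic_deviation = deviation,
                 skew = skew),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", if (x$pass) "PASS" else paste("FAIL:",
      paste(x$reasons, collapse = "; ")), "\n")
  invisible(x)
}

#' Per-replicate fold-change enrichment
#'
#' Fold change is the normalised variant frequency in the HDR-positive
#' (GFP+) pool divided by the frequency in the HDR-negative (GFP-) pool of
#' the same replicate. A pseudocount (default 0.5, Haldane-Anscombe) keeps
#' fold changes finite at zero counts:
#' `f = (count + pc) / (total + pc * n_variants)`.
#'
#' @param plus,minus [variant_count_table()]s from the same replicate.
#' @param pseudocount Pseudocount added to every count (default 0.5).
#' @return Data frame `variant_id`, `fc`.
#' @export
compute_fold_change <- function(plus, minus, pseudocount = 0.5) {
  stopifnot(inherits(plus, "variant_count_table"),
            inherits(minus, "variant_count_table"))
  if (!identical(plus$replicate, minus$replicate)) {
    stop("pools are from different replicates (",
         plus$replicate, " vs ", minus$replicate, ")")
  }
  ids <- names(plus$counts)
  if (!setequal(ids, names(minus$counts))) {
    stop("pools cover different variant sets")
  }
  cm <- minus$counts[ids]
  cp <- plus$counts[ids]
  n <- length(ids)
  fp <- (cp + pseudocount) / (plus$total_mapped + pseudocount * n)
  fm <- (cm + pseudocount) / (minus$total_mapped + pseudocount * n)
  data.frame(variant_id = ids, fc = unname(fp / fm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call screen hits from replicate fold changes
#'
#' A variant is flagged "better than parent" when its mean fold change is
#' strictly above 1.0 or every replicate fold change is strictly above 1.0.
#' Variants are ranked by mean fold change, descending; ties break
#' lexicographically by variant id. Entries whose whitelist class is
#' `stop` are excluded from ranking and flagging (they are nucleotide
#' library members, not protein variants).
#'
#' @param fold_changes Data frame `variant_id`, `fc`, `replicate` stacking
#'   [compute_fold_change()] outputs, or a list of such per-replicate frames.
#' @param whitelist Optional whitelist; used to drop `stop`-class entries.
#' @return An `enrichment_table` data frame: `variant_id`, per-replicate
#'   `fc_rep_*` columns, `mean_fc`, `better_than_parent`, `rank`.
#' @export
call_hits <- function(fold_changes, whitelist = NULL) {
  if (is.list(fold_changes) && !is.data.frame(fold_changes)) {
    fold_changes <- do.call(rbind, lapply(seq_along(fold_changes),
      function(r) cbind(fold_changes[[r]], replicate = r)))
  }
  stopifnot(all(c("variant_id", "fc", "replicate") %in% names(fold_changes)))
  if (!is.null(whitelist)) {
    stop_ids <- whitelist$variant_id[whitelist$class == "stop"]
    fold_changes <- fold_changes[!fold_changes$variant_id %in% stop_ids, ,
                                 drop = FALSE]
  }
  wide <- tapply(fold_changes$fc, fold_changes$variant_id, function(x) x,
                 simplify = FALSE)
  ids <- names(wide)
  n_rep <- max(vapply(wide, length, integer(1)))
  mat <- t(vapply(wide, function(x) c(x, rep(NA_real_, n_rep - length(x))),
                  numeric(n_rep)))
  mean_fc <- rowMeans(mat, na.rm = TRUE)
  flag <- mean_fc > 1 |
    apply(mat, 1L, function(x) all(x[!is.na(x)] > 1))
  ord <- order(-mean_fc, ids)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  out <- data.frame(variant_id = ids, mat, mean_fc = unname(mean_fc),
                    better_than_parent = unname(flag), rank = rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:(1 + n_rep)] <- paste0("fc_rep_", seq_len(n_rep))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
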