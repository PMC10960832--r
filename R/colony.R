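#' Per-colony allele count record
#'
#' @param colony_id Colony identifier.
#' @param allele_counts Named numeric vector of classified read counts per
#'   allele (`"WT"`, `"HDR"`, conversion classes, indel-species signatures).
#' @param discarded Unclassified read count.
#' @return A `colony_record`.
#' @export
colony_record <- function(colony_id, allele_counts, discarded = 0L) {
  stopifnot(is.numeric(allele_counts), !is.null(names(allele_counts)),
            all(allele_counts >= 0))
  structure(list(colony_id = colony_id, allele_counts = allele_counts,
                 aligned = sum(allele_counts),
                 discarded = as.numeric(discarded)),
            class = "colony_record")
}

#' Build a colony record by classifying its reads
#'
#' Routes a colony's reads through [tally_reads()] and maps outcome classes
#' to allele names: `WT`, `HDR`, the conversion classes, and indel-species
#' signatures. Cut-site mismatches count as the `CUTSITE_MISMATCH` allele.
#'
#' @param colony_id Colony identifier.
#' @param reads Character vector of the colony's reads.
#' @inheritParams tally_reads
#' @return A [colony_record()].
#' @export
colony_record_from_reads <- function(colony_id, reads, panel,
                                     window = quant_window(panel),
                                     params = align_params()) {
  t <- tally_reads(reads, panel, window, params)
  cl <- t$classes
  alleles <- cl[setdiff(names(cl), c("INDEL", "DISCARDED"))]
  alleles <- alleles[alleles > 0]
  if (nrow(t$species) > 0L) {
    alleles <- c(alleles, setNames(t$species$count, t$species$signature))
  }
  unassigned <- cl[["INDEL"]] - sum(t$species$count)
  if (unassigned > 0) {
    alleles <- c(alleles, INDEL_UNASSIGNED = unname(unassigned))
  }
  colony_record(colony_id, alleles, discarded = cl[["DISCARDED"]])
}

allele_is_indel <- function(allele) grepl("^[+-]?\\d+@", allele)

genotype_category <- function(a1, a2) {
  alleles <- c(a1, a2)
  if (any(alleles == "HDR")) "HDR-containing"
  else if (all(allele_is_indel(alleles))) "indel/indel"
  else if (all(alleles == "WT")) "WT/WT"
  else if (any(alleles == "WT") && any(allele_is_indel(alleles))) "WT/indel"
  else "other"
}

#' Filter a colony and call its genotype
#'
#' Filters follow the CFU-seq rules: colonies with fewer than `min_reads`
#' aligned reads are removed (`NoCall`, `low_depth`); alleles are called
#' present when their fraction of aligned reads is at least
#' `allele_fraction`; colonies with more than two present alleles are
#' removed as likely non-clonal (`NoCall`, `too_many_alleles`). Two present
#' alleles give a heterozygous call; a single present allele is called
#' homozygous by default (set `homozygous_single_allele = FALSE` to treat
#' such colonies as `NoCall` instead).
#'
#' @param record A [colony_record()].
#' @param min_reads Minimum aligned reads (default 2000).
#' @param allele_fraction Presence threshold as a fraction of aligned reads
#'   (default 0.10).
#' @param homozygous_single_allele Call single-present-allele colonies
#'   homozygous (default TRUE).
#' @return A `genotype_call`: list with `colony_id`, `allele1`, `allele2`
#'   (unordered), `category` (`HDR-containing`, `indel/indel`, `WT/WT`,
#'   `WT/indel`, `other`) or `NoCall` with `nocall_reason`.
#' @export
filter_and_call <- function(record, min_reads = 2000,
                            allele_fraction = 0.10,
                            homozygous_single_allele = TRUE) {
  stopifnot(inherits(record, "colony_record"))
  nocall <- function(reason) {
    structure(list(colony_id = record$colony_id,
                   allele1 = NA_character_, allele2 = NA_character_,
                   category = "NoCall", nocall_reason = reason),
              class = "genotype_call")
  }
  if (record$aligned < min_reads) return(nocall("low_depth"))
  frac <- record$allele_counts / record$aligned
  present <- names(frac)[frac >= allele_fraction]
  present <- present[order(-frac[present])]
  if (length(present) > 2L) return(nocall("too_many_alleles"))
  if (length(present) == 0L) return(nocall("no_allele_present"))
  if (length(present) == 1L) {
    if (!homozygous_single_allele) return(nocall("single_allele"))
    present <- rep(present, 2L)
  }
  a <- sort(present)
  structure(list(colony_id = record$colony_id,
                 allele1 = a[1], allele2 = a[2],
                 category = genotype_category(a[1], a[2]),
                 nocall_reason = NA_character_),
            class = "genotype_call")
}

#' Genotype-category rates over a set of colony calls
#'
#' Category fractions are computed over called colonies (NoCall colonies
#' are excluded from the denominator); the NoCall rate is reported over all
#' colonies. With no called colonies, rates are `NA` markers, not zeros.
#'
#' @param calls List of [filter_and_call()] results.
#' @return List with `rates` (named fractions per category),
#'   `nocall_rate`, `n_called`, `n_total`.
#' @export
genotype_rates <- function(calls) {
  if (length(calls) == 0L) stop("no colonies")
  cats <- vapply(calls, `[[`, character(1), "category")
  called <- cats != "NoCall"
  levels <- c("HDR-containing", "indel/indel", "WT/WT", "WT/indel", "other")
  rates <- if (any(called)) {
    tab <- table(factor(cats[called], levels = levels))
    setNames(as.numeric(tab) / sum(called), levels)
  } else {
    setNames(rep(NA_real_, length(levels)), levels)
  }
  list(rates = rates, nocall_rate = mean(!called),
       n_called = sum(called), n_total = length(calls))
}

#' Write genotype calls as TSV
#'
#' @param calls List of [filter_and_call()] results.
#' @param path File path.
#' @export
write_genotypes <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(g)
    data.frame(colony = g$colony_id, allele1 = g$allele1,
               allele2 = g$allele2, category = g$category,
               nocall_reason = g$nocall_reason, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
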