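#' Construct a synthetic amplicon reference panel
#'
#' Builds the five-amplicon reference set used to classify editing outcomes
#' at a Cas9 cut site: the wild-type amplicon (`WT`), the intended repair
#' outcome (`HDR`, differing from WT at the HDR SNP offsets), the fully
#' gene-converted amplicon (`HBD_FULL`, carrying all six homolog-specific
#' SNPs) and two partial conversion tracts (`HBD_PARTIAL_5P`,
#' `HBD_PARTIAL_3P`), each carrying five of the six SNPs with the tract
#' extending in the stated direction from the cut.
#'
#' The default panel embeds the HBB protospacer
#' `CTTGCCCCACAGGGCAGTAA` followed by an NGG PAM near the centre of a
#' random background sequence; the cut is the blunt SpCas9 bond 3 nt
#' 5' of the PAM. SNP offsets are synthetic: the real amplicon coordinates
#' are not published, so a layout is generated with three homolog SNPs on
#' each side of the cut and one within 2 nt of the cut bond (so the
#' cut-site-mismatch rule is exercised).
#'
#' @param seed Integer seed; the panel is deterministic given
#'   `(seed, parameters)`.
#' @param amplicon_length Amplicon length in nt (>= 80; default 142).
#' @param protospacer 20-nt protospacer embedded in WT.
#' @param pam 3-nt NGG PAM.
#' @param hdr_offsets 0-based offsets of HDR SNPs (default: one SNP 5 nt
#'   5' of the cut bond).
#' @param hbd_offsets 0-based offsets of the six homolog SNPs (default:
#'   evenly spread, `cut + c(-25, -13, -1, 5, 17, 29)`).
#' @return An `amplicon_panel`: list with `sequences` (named character
#'   vector of the 5 amplicons), `protospacer`, `pam`, `proto_start`,
#'   `cut` (0-based bond offset), `hdr_offsets`, `hbd_offsets`, `length`.
#' @export
make_panel <- function(seed = 1L, amplicon_length = 142L,
                       protospacer = "CTTGCCCCACAGGGCAGTAA",
                       pam = "TGG",
                       hdr_offsets = NULL, hbd_offsets = NULL) {
  if (amplicon_length < 80L) stop("amplicon_length must be >= 80 nt")
  stopifnot(nchar(protospacer) == 20L, nchar(pam) == 3L)
  set.seed(seed)

  site <- paste0(protospacer, pam)
  proto_start <- as.integer(floor((amplicon_length - nchar(site)) / 2))
  cut <- proto_start + 17L  # bond 3 nt 5' of the PAM, 0-based

  # background with the protospacer occurring exactly once
  for (attempt in 1:100) {
    bg <- sample(DNA_BASES, amplicon_length, replace = TRUE)
    wt <- bg
    wt[(proto_start + 1L):(proto_start + nchar(site))] <-
      strsplit(site, "")[[1]]
    wt_str <- paste(wt, collapse = "")
    if (length(gregexpr(protospacer, wt_str, fixed = TRUE)[[1]]) == 1L &&
        gregexpr(protospacer, wt_str, fixed = TRUE)[[1]][1] != -1L) break
  }

  hdr_offsets <- as.integer(hdr_offsets %||% (cut - 5L))
  hbd_offsets <- as.integer(hbd_offsets %||% (cut + c(-25L, -13L, -1L, 5L, 17L, 29L)))
  check_offsets <- function(off, what) {
    if (any(off < 0L | off >= amplicon_length)) {
      stop(what, " offsets out of amplicon bounds")
    }
    if (anyDuplicated(off)) stop(what, " offsets not distinct")
  }
  check_offsets(hdr_offsets, "HDR SNP")
  check_offsets(hbd_offsets, "homolog SNP")
  if (length(hbd_offsets) != 6L) stop("exactly 6 homolog SNP offsets required")
  if (length(intersect(hdr_offsets, hbd_offsets)) > 0L) {
    stop("HDR and homolog SNP offsets must be disjoint")
  }
  if (!any(abs(hbd_offsets - cut + 0.5) <= 2)) {
    stop("at least one homolog SNP must lie within 2 nt of the cut bond")
  }

  alt_base <- function(b) sample(setdiff(DNA_BASES, b), 1L)
  substitute_at <- function(seq_vec, offsets, alts) {
    seq_vec[offsets + 1L] <- alts
    seq_vec
  }
  hdr_alts <- vapply(wt[hdr_offsets + 1L], alt_base, character(1))
  hbd_alts <- vapply(wt[hbd_offsets + 1L], alt_base, character(1))

  hdr <- substitute_at(wt, hdr_offsets, hdr_alts)
  hbd_full <- substitute_at(wt, hbd_offsets, hbd_alts)
  ord <- order(hbd_offsets)
  # partial tracts: drop the SNP most distal in the opposite direction
  keep_3p <- ord[-1L]                 # all but the most 5' SNP
  keep_5p <- ord[-length(ord)]        # all but the most 3' SNP
  hbd_3p <- substitute_at(wt, hbd_offsets[keep_3p], hbd_alts[keep_3p])
  hbd_5p <- substitute_at(wt, hbd_offsets[keep_5p], hbd_alts[keep_5p])

  panel <- structure(
    list(sequences = c(WT = wt_str,
                       HDR = paste(hdr, collapse = ""),
                       HBD_FULL = paste(hbd_full, collapse = ""),
                       HBD_PARTIAL_5P = paste(hbd_5p, collapse = ""),
                       HBD_PARTIAL_3P = paste(hbd_3p, collapse = "")),
         protospacer = protospacer, pam = pam,
         proto_start = proto_start, cut = cut,
         hdr_offsets = sort(hdr_offsets),
         hbd_offsets = sort(hbd_offsets),
         hbd_alts = setNames(hbd_alts, hbd_offsets)[order(hbd_offsets)],
         length = as.integer(amplicon_length)),
    class = "amplicon_panel")
  validate_panel(panel)
  panel
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

validate_panel <- function(panel) {
  s <- panel$sequences
  stopifnot(length(unique(nchar(s))) == 1L)
  if (hamming(s[["WT"]], s[["HDR"]]) != length(panel$hdr_offsets)) {
    stop("HDR amplicon does not differ from WT at exactly the HDR offsets")
  }
  if (hamming(s[["WT"]], s[["HBD_FULL"]]) != 6L) {
    stop("full conversion amplicon must differ from WT at exactly 6 offsets")
  }
  if (hamming(s[["WT"]], s[["HBD_PARTIAL_5P"]]) != 5L ||
      hamming(s[["WT"]], s[["HBD_PARTIAL_3P"]]) != 5L) {
    stop("partial conversion amplicons must carry exactly 5 of the 6 SNPs")
  }
  hits <- gregexpr(panel$protospacer, s[["WT"]], fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] == -1L) {
    stop("protospacer must occur exactly once in WT")
  }
  invisible(panel)
}

#' The homolog SNP closest to the cut bond
#'
#' Used to synthesise minimal gene-conversion tracts (a lone mismatch at the
#' cut site with no indel).
#' @param panel An `amplicon_panel`.
#' @return List with `offset` and `alt` (the substituted base).
#' @export
cut_proximal_snp <- function(panel) {
  d <- abs(panel$hbd_offsets - panel$cut + 0.5)
  i <- which.min(d)
  list(offset = panel$hbd_offsets[i], alt = unname(panel$hbd_alts[i]))
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat("Amplicon panel:", x$length, "nt, cut bond at offset", x$cut, "\n")
  cat("  HDR SNPs:", paste(x$hdr_offsets, collapse = ", "),
      "| homolog SNPs:", paste(x$hbd_offsets, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a panel as FASTA plus a YAML sidecar
#'
#' @param panel An `amplicon_panel`.
#' @param fasta_path Path for the 5-record FASTA.
#' @param yaml_path Path for the metadata sidecar (cut index, SNP offsets).
#' @export
write_panel <- function(panel, fasta_path, yaml_path) {
  seqs <- Biostrings::DNAStringSet(panel$sequences)
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- list(protospacer = panel$protospacer, pam = panel$pam,
               proto_start = panel$proto_start, cut = panel$cut,
               hdr_offsets = as.list(panel$hdr_offsets),
               hbd_offsets = as.list(panel$hbd_offsets),
               hbd_alts = as.list(unname(panel$hbd_alts)),
               length = panel$length)
  yaml::write_yaml(meta, yaml_path)
  invisible(fasta_path)
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta_path, yaml_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- yaml::read_yaml(yaml_path)
  hbd_offsets <- as.integer(unlist(meta$hbd_offsets))
  panel <- structure(
    list(sequences = setNames(as.character(seqs), names(seqs)),
         protospacer = meta$protospacer, pam = meta$pam,
         proto_start = as.integer(meta$proto_start),
         cut = as.integer(meta$cut),
         hdr_offsets = as.integer(unlist(meta$hdr_offsets)),
         hbd_offsets = hbd_offsets,
         hbd_alts = setNames(as.character(unlist(meta$hbd_alts)),
                             hbd_offsets),
         length = as.integer(meta$length)),
    class = "amplicon_panel")
  validate_panel(panel)
  panel
}
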