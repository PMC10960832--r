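#' Fixed one-codon-per-amino-acid table
#'
#' Returns the codon table used to encode combinatorial protein variant
#' libraries: exactly one codon per standard amino acid, chosen so that every
#' library member has a unique, predictable coding sequence.
#'
#' @return Named character vector mapping one-letter amino-acid codes to
#'   3-letter DNA codons.
#' @export
#' @examples
#' one_codon_table()[["A"]]  # "GCA"
one_codon_table <- function() {
  c(A = "GCA", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
    G = "GGT", H = "CAC", I = "ATA", K = "AAA", L = "CTC",
    M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGG",
    S = "AGC", T = "ACC", V = "GTC", W = "TGG", Y = "TAT")
}

#' Codon for an amino acid under the fixed table
#'
#' @param aa One-letter amino-acid code (one of the 20 standard residues).
#' @return 3-letter DNA codon.
#' @export
codon_for <- function(aa) {
  stopifnot(is.character(aa), length(aa) == 1L)
  tab <- one_codon_table()
  if (!aa %in% names(tab)) {
    stop("'", aa, "' is not a standard one-letter amino-acid code")
  }
  unname(tab[[aa]])
}

# Translate a DNA coding sequence with the standard genetic code.
# Stops are "*".
translate_dna <- function(dna) {
  stopifnot(nchar(dna) %% 3L == 0L)
  if (nchar(dna) == 0L) return("")
  codons <- substring(dna, seq(1L, nchar(dna), by = 3L),
                      seq(3L, nchar(dna), by = 3L))
  aas <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aas)) stop("sequence contains an untranslatable codon")
  paste(aas, collapse = "")
}

# All 32 NNK codons: positions 1-2 any base, position 3 in {G,T}.
nnk_codons <- function() {
  g <- expand.grid(b3 = c("G", "T"), b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

parent_checks <- function(parent_dna, positions) {
  stopifnot(is.character(parent_dna), length(parent_dna) == 1L)
  parent_dna <- toupper(parent_dna)
  if (nchar(parent_dna) %% 3L != 0L) {
    stop("parent coding sequence length is not divisible by 3 (not in frame)")
  }
  n_res <- nchar(parent_dna) / 3L
  if (any(positions < 1L | positions > n_res)) {
    stop("position out of range: parent has ", n_res, " codons")
  }
  if (anyDuplicated(positions)) stop("duplicate positions")
  parent_dna
}

codon_at <- function(dna, position) {
  substr(dna, 3L * (position - 1L) + 1L, 3L * position)
}

replace_codons <- function(dna, positions, codons) {
  for (k in seq_along(positions)) {
    substr(dna, 3L * (positions[k] - 1L) + 1L, 3L * positions[k]) <- codons[k]
  }
  dna
}

new_variant_library <- function(parent_dna, positions, scheme, members) {
  structure(
    list(parent_dna = parent_dna,
         parent_protein = translate_dna(parent_dna),
         positions = as.integer(positions),
         scheme = scheme,
         members = members),
    class = "variant_library")
}

#' @export
print.variant_library <- function(x, ...) {
  cat("Variant library (", x$scheme, ") at position(s) ",
      paste(x$positions, collapse = ", "), ": ",
      nrow(x$members), " members\n", sep = "")
  invisible(x)
}

#' Enumerate an NNK saturation-mutagenesis library at one position
#'
#' Replaces the codon at `position` of the parent coding sequence with each of
#' the 32 NNK codons (N = any base, K = G/T). The 32 codons encode all 20
#' amino acids plus one stop (TAG); the stop codon is retained in the
#' nucleotide listing under the reserved variant id `"STOP"` so that reads
#' carrying it can still be counted, but it is excluded from protein-level
#' ranking downstream. NNK codons that restore the parent amino acid through
#' a codon other than the parent's own are internal-control members, distinct
#' from the parent carry-over entry (the parent's own codon, which is
#' appended if it is not itself an NNK codon).
#'
#' Screens resolve individual codons, so an amino acid encoded by several
#' NNK codons yields one member per codon; ids are codon-qualified where
#' needed (e.g. `"L67R.CGG"`).
#'
#' @param parent_dna Parent coding DNA sequence (length divisible by 3).
#' @param position 1-based residue index to saturate.
#' @return A `variant_library` with a `members` data frame (columns
#'   `variant_id`, `aa_id` (protein-level id), `codons`, `dna`, `protein`,
#'   `class`).
#' @export
enumerate_nnk <- function(parent_dna, position) {
  parent_dna <- parent_checks(parent_dna, position)
  parent_codon <- codon_at(parent_dna, position)
  parent_aa <- Biostrings::GENETIC_CODE[[parent_codon]]

  codons <- nnk_codons()
  if (!parent_codon %in% codons) codons <- c(codons, parent_codon)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  dna <- vapply(codons, function(cd) replace_codons(parent_dna, position, cd),
                character(1))
  aa_id <- ifelse(aa == "*", "STOP", paste0(parent_aa, position, aa))
  multi <- aa_id %in% aa_id[duplicated(aa_id)]
  variant_id <- ifelse(multi, paste0(aa_id, ".", codons), aa_id)
  class <- ifelse(aa == "*", "stop",
           ifelse(codons == parent_codon, "parent",
           ifelse(aa == parent_aa, "internal_control", "member")))
  members <- data.frame(variant_id = variant_id, aa_id = aa_id,
                        codons = codons, dna = dna,
                        protein = vapply(dna, translate_dna, character(1)),
                        class = class, row.names = NULL,
                        stringsAsFactors = FALSE)
  new_variant_library(parent_dna, position, "NNK", members)
}

#' Enumerate a combinatorial variant library
#'
#' Builds the Cartesian product of an amino-acid alphabet over a set of
#' residue positions, encoding each residue by its fixed codon from
#' [one_codon_table()]. For a two-position library this yields
#' `|alphabet|^2` members (324 when cysteine and methionine are excluded,
#' 400 for the full alphabet).
#'
#' @param parent_dna Parent coding DNA sequence (length divisible by 3).
#' @param positions 1-based residue indices to vary (distinct).
#' @param alphabet Amino-acid alphabet; defaults to the 20 standard residues.
#' @return A `variant_library`; member ids are dot-separated substitutions in
#'   residue order (e.g. `"T12V.T14H"`). A member identical in protein to the
#'   parent gets id `"parent"`.
#' @export
enumerate_combinatorial <- function(parent_dna, positions,
                                    alphabet = AA_STANDARD) {
  parent_dna <- parent_checks(parent_dna, positions)
  if (length(alphabet) == 0L) stop("empty alphabet")
  if (!all(alphabet %in% AA_STANDARD)) {
    stop("alphabet contains non-standard residues: ",
         paste(setdiff(alphabet, AA_STANDARD), collapse = ", "))
  }
  positions <- as.integer(positions)
  parent_aas <- vapply(positions, function(p)
    Biostrings::GENETIC_CODE[[codon_at(parent_dna, p)]], character(1))

  combos <- expand.grid(rep(list(alphabet), length(positions)),
                        stringsAsFactors = FALSE)
  combos <- combos[do.call(order, combos), , drop = FALSE]
  tab <- one_codon_table()

  build_one <- function(aas) {
    codons <- unname(tab[aas])
    dna <- replace_codons(parent_dna, positions, codons)
    subs <- aas != parent_aas
    id <- if (any(subs)) {
      paste0(parent_aas[subs], positions[subs], aas[subs], collapse = ".")
    } else "parent"
    list(id = id, codons = paste(codons, collapse = ","), dna = dna)
  }
  built <- apply(combos, 1L, function(row) build_one(as.character(row)))
  dna <- vapply(built, `[[`, character(1), "dna")
  protein <- vapply(dna, translate_dna, character(1))
  class <- ifelse(dna == parent_dna, "parent",
           ifelse(protein == translate_dna(parent_dna),
                  "internal_control", "member"))
  members <- data.frame(
    variant_id = vapply(built, `[[`, character(1), "id"),
    codons = vapply(built, `[[`, character(1), "codons"),
    dna = dna, protein = protein, class = class,
    row.names = NULL, stringsAsFactors = FALSE)
  if (anyDuplicated(members$variant_id)) stop("member ids not unique")
  new_variant_library(parent_dna, positions, "combinatorial", members)
}

#' Build the screen whitelist from a variant library
#'
#' The whitelist maps every member coding sequence to its variant id and
#' class; screen counting matches reads against it exactly. Parent carry-over
#' (the parent's own codon) and internal-control entries (parent amino acid
#' from a non-parent codon) are flagged so that QC can compare their
#' abundances.
#'
#' @param library A `variant_library`.
#' @param parent_carryover Also whitelist the unmutated parent coding
#'   sequence (class `parent`, id `parent_carryover`) when it is not
#'   already a library member; real pools always contain carried-over
#'   parent template. Default `FALSE` (the whitelist then covers exactly
#'   the designed members).
#' @return Data frame with columns `dna_sequence`, `variant_id`, `class`,
#'   of S3 class `whitelist`.
#' @export
build_whitelist <- function(library, parent_carryover = FALSE) {
  stopifnot(inherits(library, "variant_library"))
  m <- library$members
  if (nrow(m) == 0L) stop("library is empty")
  wl <- data.frame(dna_sequence = m$dna, variant_id = m$variant_id,
                   class = m$class, row.names = NULL,
                   stringsAsFactors = FALSE)
  if (parent_carryover && !library$parent_dna %in% wl$dna_sequence) {
    wl <- rbind(wl, data.frame(dna_sequence = library$parent_dna,
                               variant_id = "parent_carryover",
                               class = "parent", stringsAsFactors = FALSE))
  }
  dup <- duplicated(wl$dna_sequence)
  if (any(dup)) {
    clash <- wl$dna_sequence %in% wl$dna_sequence[dup]
    ids <- tapply(wl$variant_id[clash], wl$dna_sequence[clash],
                  function(x) length(unique(x)))
    if (any(ids > 1L)) {
      stop("duplicate DNA sequences map to different variant ids")
    }
    wl <- wl[!dup, , drop = FALSE]
  }
  class(wl) <- c("whitelist", "data.frame")
  wl
}

#' Write / read a whitelist as TSV
#'
#' @param whitelist A `whitelist` data frame.
#' @param path File path.
#' @export
write_whitelist <- function(whitelist, path) {
  stopifnot(inherits(whitelist, "whitelist"))
  write.table(whitelist, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  wl <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("dna_sequence", "variant_id", "class")
  if (!all(need %in% names(wl))) {
    stop("whitelist TSV must have columns: ", paste(need, collapse = ", "))
  }
  class(wl) <- c("whitelist", "data.frame")
  wl
}
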