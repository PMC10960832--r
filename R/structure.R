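#' Load a structure model from PDB or mmCIF
#'
#' Reads the first model, resolves alternate locations by keeping the
#' highest-occupancy altloc per (chain, residue, atom name), and retains
#' waters (needed to inspect water-mediated hydrogen bonds). Parsing is
#' delegated to bio3d.
#'
#' @param file Path to a `.pdb`/`.ent` or `.cif` file.
#' @return A `structure_model`: list with `atoms` (data frame `chain`,
#'   `resno`, `resid`, `atom`, `element`, `x`, `y`, `z`, `occupancy`) and
#'   `model_id`.
#' @export
load_structure <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  is_cif <- grepl("\\.cif(\\.gz)?$", file, ignore.case = TRUE)
  parsed <- tryCatch(
    # read.cif warns unconditionally about its beta status; silence that
    if (is_cif) suppressWarnings(bio3d::read.cif(file, multi = FALSE))
    else bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse coordinate file '", file,
                             "': ", conditionMessage(e)))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in ", file)
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resid = as.character(a$resid), atom = as.character(a$elety),
    element = as.character(a$elesy %||% substr(trimws(a$elety), 1L, 1L)),
    x = a$x, y = a$y, z = a$z,
    occupancy = if (!is.null(a$o)) a$o else 1,
    alt = if (!is.null(a$alt)) as.character(a$alt) else NA_character_,
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", file)
  }
  # altloc resolution: highest occupancy wins per (chain, resno, atom)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "|")
  ord <- order(key, -atoms$occupancy)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = basename(file)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model", x$model_id, ":", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Select atoms by chain, residue number and atom names
#'
#' @param chain Chain id.
#' @param resno Residue number.
#' @param atoms Character vector of atom names (e.g. `c("NH1","NH2","NE")`
#'   for an arginine guanidinium); `NULL` selects all atoms of the residue.
#' @return An `atom_selection`.
#' @export
atom_selection <- function(chain, resno, atoms = NULL) {
  structure(list(chain = chain, resno = as.integer(resno), atoms = atoms),
            class = "atom_selection")
}

resolve_selection <- function(model, sel) {
  a <- model$atoms
  rows <- a$chain == sel$chain & a$resno == sel$resno
  if (!is.null(sel$atoms)) rows <- rows & a$atom %in% sel$atoms
  hit <- a[rows, , drop = FALSE]
  if (nrow(hit) == 0L) {
    avail <- a$atom[a$chain == sel$chain & a$resno == sel$resno]
    stop("selection ", sel$chain, ":", sel$resno,
         if (!is.null(sel$atoms)) paste0(":", paste(sel$atoms, collapse = ",")),
         " resolves to no atoms; available atoms for that residue: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  hit
}

# round-half-up (not banker's): 2.85 -> 2.9 at digits = 1
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Minimum pairwise distance between two atom selections
#'
#' Euclidean minimum over the Cartesian product of the two selections,
#' reported rounded half-up to 0.1 A with the achieving atom pair.
#'
#' @param model A [load_structure()] model.
#' @param selA,selB [atom_selection()]s (each must resolve to >= 1 atom).
#' @return A `distance_result`: list with `distance` (rounded to 0.1 A),
#'   `distance_raw`, `atom_a`, `atom_b`.
#' @export
min_distance <- function(model, selA, selB) {
  a <- resolve_selection(model, selA)
  b <- resolve_selection(model, selB)
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(bm^2), "+") - 2 * am %*% t(bm)
  d2[d2 < 0] <- 0
  k <- arrayInd(which.min(d2), dim(d2))
  dmin <- sqrt(d2[k])
  lab <- function(df, i) paste0(df$chain[i], ":", df$resid[i], df$resno[i],
                                ":", df$atom[i])
  structure(list(distance = round_half_up(dmin, 1L), distance_raw = dmin,
                 atom_a = lab(a, k[1]), atom_b = lab(b, k[2])),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("%.1f A between %s and %s", x$distance, x$atom_a, x$atom_b))
  if (!is.null(x$hbond)) cat(" | H-bond:", x$hbond)
  cat("\n")
  invisible(x)
}

#' Heavy-atom hydrogen-bond check
#'
#' Declares an H-bond when the minimum heavy-atom distance between donor
#' and acceptor selections is at or below `cutoff` (default 3.5 A). No
#' hydrogen positions or donor-H...acceptor angles are used: deposited
#' structures at typical resolution lack hydrogens.
#'
#' @inheritParams min_distance
#' @param donor,acceptor [atom_selection()]s.
#' @param cutoff Distance cutoff in Angstrom (default 3.5).
#' @return A `distance_result` with an `hbond` logical verdict.
#' @export
hbond_check <- function(model, donor, acceptor, cutoff = 3.5) {
  res <- min_distance(model, donor, acceptor)
  res$hbond <- res$distance_raw <= cutoff
  res$cutoff <- cutoff
  res
}

#' Verify the reported i53:53BP1 interface contacts
#'
#' Computes the two published interface hydrogen-bond distances from
#' user-downloaded coordinate files: the arginine-67 guanidinium to
#' aspartate-1550 carboxylate contact (entry 8SVH) and the glutamate-14
#' carboxylate to tyrosine-1502 hydroxyl contact (entry 8T2D). The
#' accession files are not bundled; download them (e.g. from the PDB) into
#' `dir` first. Chains are auto-detected: the 53BP1 Tudor chain is the one
#' containing residue numbers near 1550, the inhibitor chain the one
#' containing residue 67.
#'
#' @param dir Directory containing `8SVH.pdb`/`.cif` and `8T2D.pdb`/`.cif`.
#' @param cutoff H-bond cutoff in Angstrom.
#' @return Data frame `entry`, `contact`, `distance`, `atom_a`, `atom_b`,
#'   `hbond`.
#' @export
verify_reported_contacts <- function(dir, cutoff = 3.5) {
  find_file <- function(acc) {
    cands <- file.path(dir, paste0(acc, c(".pdb", ".ent", ".cif")))
    hit <- cands[file.exists(cands)]
    if (length(hit) == 0L) {
      stop("no coordinate file for ", acc, " under ", dir,
           "; download it first (no network access is performed here)")
    }
    hit[1]
  }
  chain_with_resno <- function(model, resno) {
    ch <- unique(model$atoms$chain[model$atoms$resno == resno &
                                     model$atoms$resid != "HOH"])
    if (length(ch) == 0L) stop("no chain contains residue ", resno)
    ch[1]
  }
  contact <- function(acc, res_i, atoms_i, res_t, atoms_t, label) {
    model <- load_structure(find_file(acc))
    ci <- chain_with_resno(model, res_i)
    ct <- chain_with_resno(model, res_t)
    r <- hbond_check(model, atom_selection(ci, res_i, atoms_i),
                     atom_selection(ct, res_t, atoms_t), cutoff)
    data.frame(entry = acc, contact = label, distance = r$distance,
               atom_a = r$atom_a, atom_b = r$atom_b, hbond = r$hbond,
               stringsAsFactors = FALSE)
  }
  rbind(
    contact("8SVH", 67L, c("NE", "NH1", "NH2"), 1550L, c("OD1", "OD2"),
            "R67 guanidinium - D1550 carboxylate"),
    contact("8T2D", 14L, c("OE1", "OE2"), 1502L, "OH",
            "E14 carboxylate - Y1502 hydroxyl"))
}
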