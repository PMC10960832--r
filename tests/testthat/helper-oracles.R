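# Independent oracles and shared fixtures, built in code.

# Exhaustive three-state affine-gap DP (score only), written independently
# of the package's C++ aligner. Gap of length L scores go + L * ge.
gotoh_score_oracle <- function(read, ref, ma = 5, mi = -4, go = -20,
                               ge = -2) {
  r <- strsplit(read, "")[[1]]
  q <- strsplit(ref, "")[[1]]
  n <- length(r)
  m <- length(q)
  M <- matrix(-Inf, n + 1, m + 1)
  D <- matrix(-Inf, n + 1, m + 1)
  I <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) D[1, j] <- go + (j - 1) * ge
  for (i in 2:(n + 1)) I[i, 1] <- go + (i - 1) * ge
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (r[i - 1] == q[j - 1] && r[i - 1] != "N") ma else mi
      M[i, j] <- max(M[i - 1, j - 1], D[i - 1, j - 1], I[i - 1, j - 1]) + s
      D[i, j] <- max(M[i, j - 1] + go + ge, D[i, j - 1] + ge,
                     I[i, j - 1] + go + ge)
      I[i, j] <- max(M[i - 1, j] + go + ge, D[i - 1, j] + go + ge,
                     I[i - 1, j] + ge)
    }
  }
  max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[o][i:m] / (i:m))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Small shared panel (100 nt keeps alignment tests fast)
test_panel <- function() make_panel(seed = 42L, amplicon_length = 100L)

# A 9-codon parent whose codon 2 (CTG) is itself an NNK codon
nnk_parent <- paste0("ATG", "CTG", "GAG", "AAA", "TTC", "GGT", "CAC",
                     "ATA", "TGG")

# Deterministic read set: exact template multiplicities, no sampling
reads_exact <- function(panel, spec_counts, species = list()) {
  out <- character(0)
  for (nm in names(spec_counts)) {
    template <- if (nm %in% names(species)) {
      ampedit:::apply_species(panel, species[[nm]])
    } else {
      ampedit:::class_template(nm, panel)
    }
    out <- c(out, rep(template, spec_counts[[nm]]))
  }
  names(out) <- paste0("read_", seq_along(out))
  out
}
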