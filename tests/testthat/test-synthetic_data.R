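test_that("panel construction satisfies its sequence invariants deterministically", {
  p <- test_panel()
  s <- p$sequences
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(ham(s[["WT"]], s[["HBD_FULL"]]), 6L)
  expect_equal(ham(s[["WT"]], s[["HBD_PARTIAL_5P"]]), 5L)
  expect_equal(ham(s[["WT"]], s[["HBD_PARTIAL_3P"]]), 5L)
  expect_equal(ham(s[["WT"]], s[["HDR"]]), length(p$hdr_offsets))
  expect_equal(length(unique(nchar(s))), 1L)
  # protospacer exactly once, cut 3 nt 5' of the PAM
  hits <- gregexpr(p$protospacer, s[["WT"]], fixed = TRUE)[[1]]
  expect_equal(length(hits), 1L)
  expect_equal(p$cut, p$proto_start + 17L)
  expect_identical(make_panel(seed = 42L, amplicon_length = 100L), p)
  expect_false(identical(make_panel(seed = 43L, amplicon_length = 100L)$sequences[["WT"]],
                         s[["WT"]]))
})

test_that("panel rejects invalid SNP layouts", {
  expect_error(make_panel(seed = 1, amplicon_length = 60L), ">= 80")
  expect_error(make_panel(seed = 1, hbd_offsets = c(1:5, 140L)),
               "within 2 nt")
  expect_error(make_panel(seed = 1, hbd_offsets = 70:74), "6 homolog")
})

test_that("panel round-trips through FASTA + YAML sidecar", {
  p <- test_panel()
  fa <- withr::local_tempfile(fileext = ".fa")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_panel(p, fa, yml)
  p2 <- read_panel(fa, yml)
  expect_equal(p2$sequences, p$sequences)
  expect_equal(p2$cut, p$cut)
  expect_equal(p2$hbd_offsets, p$hbd_offsets)
})

test_that("noise-free single-class mixtures reproduce the template exactly", {
  p <- test_panel()
  mix <- truth_mixture(c(WT = 1.0))
  sim <- simulate_reads(p, mix, 100L, seed = 3L)
  expect_true(all(sim$reads == p$sequences[["WT"]]))
  expect_true(all(sim$truth$class == "WT"))
})

test_that("mixture sampling is multinomial within 3 SDs and truth labels are consistent", {
  p <- test_panel()
  sp <- indel_species(-1L, 0L)
  mix <- truth_mixture(c(WT = 0.5, HDR = 0.3, "-1@0" = 0.2),
                       species = list(sp))
  n <- 10000L
  sim <- simulate_reads(p, mix, n, seed = 7L)
  counts <- table(factor(sim$truth$class, levels = names(mix$proportions)))
  for (cl in names(mix$proportions)) {
    pr <- mix$proportions[[cl]]
    expect_lt(abs(counts[[cl]] - n * pr), 3 * sqrt(n * pr * (1 - pr)) + 1)
  }
  # truth consistency at zero noise: reads equal their class template
  templates <- c(WT = p$sequences[["WT"]], HDR = p$sequences[["HDR"]],
                 "-1@0" = ampedit:::apply_species(p, sp))
  expect_true(all(sim$reads == templates[sim$truth$class]))
})

test_that("substitution noise hits at the configured rate", {
  p <- test_panel()
  eps <- 0.001
  mix <- truth_mixture(c(WT = 1.0), error_rate = eps)
  n <- 10000L
  sim <- simulate_reads(p, mix, n, seed = 11L)
  wt <- strsplit(p$sequences[["WT"]], "")[[1]]
  mismatches <- vapply(sim$reads, function(r)
    sum(strsplit(r, "")[[1]] != wt), numeric(1))
  total <- n * length(wt)
  expect_lt(abs(sum(mismatches) - total * eps),
            3 * sqrt(total * eps * (1 - eps)))
})

test_that("generators are bit-reproducible for a fixed seed", {
  p <- test_panel()
  mix <- truth_mixture(c(WT = 0.6, HDR = 0.4), error_rate = 0.01)
  expect_identical(simulate_reads(p, mix, 500L, seed = 5L),
                   simulate_reads(p, mix, 500L, seed = 5L))
  wl <- build_whitelist(enumerate_nnk(nnk_parent, 2L))
  tr <- screen_truth(wl, n_reps = 2L, depth = 1e4)
  expect_identical(simulate_screen_counts(tr, seed = 9L),
                   simulate_screen_counts(tr, seed = 9L))
})

test_that("screen count simulation respects depth and errors on zero depth", {
  wl <- build_whitelist(enumerate_nnk(nnk_parent, 2L))
  tr <- screen_truth(wl, n_reps = 2L, depth = 5e4)
  cnt <- simulate_screen_counts(tr, seed = 1L)
  expect_length(cnt, 2L)
  expect_equal(cnt[[1]]$plus$total_mapped, 5e4)
  expect_equal(cnt[[2]]$minus$total_mapped, 5e4)
  expect_error(simulate_screen_counts(screen_truth(wl, depth = 0), seed = 1),
               "depth")
})

test_that("POLQ knockdown arms scale targeted species and zero removes them", {
  mix <- truth_mixture(c(WT = 0.6, "-4@-2" = 0.3, "-1@0" = 0.1),
                       species = list(indel_species(-4L, -2L,
                                                    polq_dependent = TRUE),
                                      indel_species(-1L, 0L)))
  arms <- simulate_polq_arms(mix, c("-4@-2" = 0), n_reps = 3L,
                             depth = 1e4, seed = 2L)
  kd <- arms[arms$arm == "knockdown" & arms$class == "-4@-2", ]
  expect_true(all(kd$count == 0))
  ctrl <- arms[arms$arm == "control" & arms$class == "-4@-2", ]
  expect_true(all(ctrl$count > 0))
  expect_warning(simulate_polq_arms(mix, n_reps = 1L, depth = 100,
                                    seed = 1L), "undefined")
  expect_error(simulate_polq_arms(mix, c("+9@9:AAAAAAAAA" = 0.5),
                                  depth = 10, seed = 1), "unknown class")
})

test_that("simulated colonies carry coherent truth flags and balanced alleles", {
  p <- test_panel()
  gd <- list(pairs = list(c("HDR", "WT"), c("WT", "WT")), probs = c(0.5, 0.5))
  sim <- simulate_colonies(20L, gd, depth_distribution = 5000L,
                           contamination_rate = 0, panel = p, seed = 4L)
  expect_true(all(is.na(sim$truth$allele3)))
  expect_true(all(!sim$truth$expected_filtered))
  het <- which(sim$truth$allele1 == "HDR")
  hdr_seq <- p$sequences[["HDR"]]
  for (i in het) {
    frac <- mean(sim$reads[[i]] == hdr_seq)
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 5000))
  }
  # low-depth colonies are truth-flagged for filtering
  sim2 <- simulate_colonies(10L, gd, depth_distribution = c(1500L, 4000L),
                            contamination_rate = 0, panel = p, seed = 8L)
  expect_identical(sim2$truth$expected_filtered, sim2$truth$depth < 2000L)
  expect_error(simulate_colonies(5L, list(pairs = list(), probs = numeric(0)),
                                 panel = p), "empty genotype")
})
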