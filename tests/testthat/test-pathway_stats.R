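mk_design <- function(species, kd, ctrl) {
  do.call(rbind, lapply(seq_along(species), function(i)
    rbind(data.frame(class = species[i], arm = "knockdown",
                     replicate = seq_along(kd[[i]]), fraction = kd[[i]]),
          data.frame(class = species[i], arm = "control",
                     replicate = seq_along(ctrl[[i]]),
                     fraction = ctrl[[i]]))))
}

test_that("the one-sided Welch p-value matches an independent t-CDF evaluation", {
  kd <- c(0.02, 0.021)
  ctrl <- c(0.10, 0.11)
  d <- paired_design(mk_design("-1@0", list(kd), list(ctrl)))
  calls <- classify_mmej(d, alpha = 0.1, min_control_fraction = 0)
  # independent Welch computation from the textbook formula
  se <- sqrt(var(ctrl) / 2 + var(kd) / 2)
  tstat <- (mean(ctrl) - mean(kd)) / se
  df <- se^4 / ((var(ctrl) / 2)^2 / 1 + (var(kd) / 2)^2 / 1)
  expect_equal(calls$p, stats::pt(tstat, df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(calls$p, 0.05)
  expect_identical(calls$label, "MMEJ")
})

test_that("identical arms give p = 0.5 and are never flagged", {
  d <- paired_design(mk_design("-1@0", list(c(0.1, 0.1)), list(c(0.1, 0.1))))
  calls <- classify_mmej(d, min_control_fraction = 0)
  expect_equal(calls$p, 0.5)
  expect_identical(calls$label, "NHEJ")
})

test_that("BH adjustment follows the step-up rule and matches the oracle", {
  p <- c(0.01, 0.04, 0.20)
  expect_equal(stats::p.adjust(p, "BH"), c(0.03, 0.06, 0.20))
  expect_equal(bh_oracle(p), c(0.03, 0.06, 0.20))
  set.seed(55)
  for (k in 1:200) {
    pv <- runif(sample(1:20, 1))
    expect_equal(stats::p.adjust(pv, "BH"), bh_oracle(pv))
  }
})

test_that("species below the control-fraction floor or with <2 replicates stay untested NHEJ", {
  d <- paired_design(mk_design(c("-1@0", "-2@0"),
                               list(c(0.0001, 0.0002), c(0.05)),
                               list(c(0.0004, 0.0005), c(0.20))))
  calls <- classify_mmej(d)
  low <- calls[calls$species == "-1@0", ]
  expect_false(low$tested)
  expect_identical(low$label, "NHEJ")
  expect_match(low$reason, "minimum control fraction")
  few <- calls[calls$species == "-2@0", ]
  expect_false(few$tested)
  expect_match(few$reason, "fewer than 2")
})

test_that("length-only collapse pools same-length species within arm and replicate", {
  d <- paired_design(mk_design(c("-1@0", "-1@-2", "+2@0:CA"),
                               list(c(0.01, 0.02), c(0.03, 0.04),
                                    c(0.05, 0.06)),
                               list(c(0.02, 0.03), c(0.04, 0.05),
                                    c(0.06, 0.07))))
  cd <- collapse_species_by_length(d)
  expect_setequal(unique(cd$class), c("-1", "+2"))
  r1 <- cd[cd$class == "-1" & cd$arm == "knockdown" & cd$replicate == 1, ]
  expect_equal(r1$fraction, 0.01 + 0.03)
  calls <- classify_mmej(cd, min_control_fraction = 0)
  expect_setequal(calls$species, c("-1", "+2"))
})

test_that("outcome summaries follow the all-allele and edited-allele arithmetic", {
  panel <- test_panel()
  window <- quant_window(panel)
  reads <- reads_exact(panel, c(WT = 50L, HDR = 30L, "-1@0" = 20L),
                       species = list("-1@0" = indel_species(-1L, 0L)))
  t <- tally_reads(reads, panel, window)
  s <- summarize_outcomes(t)
  expect_equal(unname(s$all_alleles[["HDR"]]), 30)
  expect_equal(unname(s$all_alleles[["WT"]]), 50)
  expect_equal(unname(s$all_alleles[["NHEJ"]]), 20)
  expect_equal(unname(s$edited_alleles[["HDR"]]), 60)  # 30/(100-50)*100
  expect_equal(sum(s$all_alleles), 100)

  # all-WT sample: edited-allele view unavailable, not zero
  s2 <- summarize_outcomes(tally_reads(reads_exact(panel, c(WT = 10L)),
                                       panel, window))
  expect_true(all(is.na(s2$edited_alleles)))
  expect_equal(unname(s2$all_alleles[["WT"]]), 100)
})

test_that("MMEJ calls route species counts into the %MMEJ bucket", {
  panel <- test_panel()
  window <- quant_window(panel)
  reads <- reads_exact(panel, c(WT = 40L, "-4@-2" = 30L, "-1@0" = 30L),
                       species = list("-4@-2" = indel_species(-4L, -2L),
                                      "-1@0" = indel_species(-1L, 0L)))
  t <- tally_reads(reads, panel, window)
  calls <- data.frame(species = c("-4@-2", "-1@0"), p = c(0.001, 0.6),
                      q = c(0.002, 0.6), label = c("MMEJ", "NHEJ"),
                      tested = TRUE, reason = NA_character_)
  s <- summarize_outcomes(t, calls)
  expect_equal(unname(s$all_alleles[["MMEJ"]]), 30)
  expect_equal(unname(s$all_alleles[["NHEJ"]]), 30)
  expect_equal(sum(s$all_alleles), 100)
})

test_that("summary percentages always sum to 100 on random mixtures", {
  panel <- test_panel()
  window <- quant_window(panel)
  set.seed(66)
  for (k in 1:5) {
    pr <- as.numeric(rmultinom(1, 200, rep(1, 5)))
    counts <- setNames(pmax(pr, 1),
                       c("WT", "HDR", "HBD_FULL", "CUTSITE_MISMATCH",
                         "-1@0"))
    reads <- reads_exact(panel, counts,
                         species = list("-1@0" = indel_species(-1L, 0L)))
    s <- summarize_outcomes(tally_reads(reads, panel, window))
    expect_equal(sum(s$all_alleles), 100, tolerance = 1e-6)
  }
})

test_that("inhibition by length class applies 100*(1 - treated/control) with sign", {
  panel <- test_panel()
  window <- quant_window(panel)
  species <- list("-1@0" = indel_species(-1L, 0L),
                  "+2@0:CA" = indel_species(2L, 0L, "CA"),
                  "-7@-3" = indel_species(-7L, -3L))
  ctrl_reads <- reads_exact(panel, c(WT = 80L, "-1@0" = 10L, "-7@-3" = 10L),
                            species = species)
  trt_reads <- reads_exact(panel, c(WT = 90L, "-1@0" = 5L, "-7@-3" = 5L),
                           species = species)
  ctrl <- summarize_outcomes(tally_reads(ctrl_reads, panel, window))
  trt <- summarize_outcomes(tally_reads(trt_reads, panel, window))
  rep <- inhibition_by_length(trt, ctrl)
  listed <- rep[rep$length_class != "other lengths", ]
  expect_equal(listed$fraction_control, 0.10)
  expect_equal(listed$fraction_treated, 0.05)
  expect_equal(listed$inhibition_pct, 50)
  other <- rep[rep$length_class == "other lengths", ]
  expect_equal(other$inhibition_pct, 50)

  # identical summaries: zero inhibition
  rep0 <- inhibition_by_length(ctrl, ctrl)
  expect_true(all(rep0$inhibition_pct == 0))

  # enrichment reports as negative inhibition
  enr_reads <- reads_exact(panel, c(WT = 76L, "-1@0" = 12L, "-7@-3" = 12L),
                           species = species)
  enr <- summarize_outcomes(tally_reads(enr_reads, panel, window))
  rep_neg <- inhibition_by_length(enr, ctrl)
  expect_equal(rep_neg$inhibition_pct[1], -20)

  # MMEJ species are excluded from both sides
  calls <- data.frame(species = "-7@-3", p = 0.001, q = 0.002,
                      label = "MMEJ", tested = TRUE, reason = NA_character_)
  ctrl_m <- summarize_outcomes(tally_reads(ctrl_reads, panel, window), calls)
  trt_m <- summarize_outcomes(tally_reads(trt_reads, panel, window), calls)
  rep_m <- inhibition_by_length(trt_m, ctrl_m)
  expect_equal(rep_m$fraction_control[2], 0)  # -7 was the only 'other'
  expect_true(is.na(rep_m$inhibition_pct[2]))
})
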