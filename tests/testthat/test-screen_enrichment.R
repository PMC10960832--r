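wl_nnk <- build_whitelist(enumerate_nnk(nnk_parent, 2L))

test_that("read counting is exact-match only and conserves reads", {
  key <- wl_nnk$dna_sequence[5]
  near <- key
  substr(near, 1, 1) <- ifelse(substr(key, 1, 1) == "A", "C", "A")
  tab <- count_variants(c(key, key, key, near), wl_nnk)
  expect_equal(unname(tab$counts[wl_nnk$variant_id[5]]), 3)
  expect_equal(tab$discarded, 1)
  expect_equal(tab$total_mapped + tab$discarded, 4)
  empty <- count_variants(character(0), wl_nnk)
  expect_equal(empty$total_mapped, 0)
  expect_equal(empty$discarded, 0)
})

test_that("stop-codon reads can be counted in totals or discarded", {
  stop_key <- wl_nnk$dna_sequence[wl_nnk$class == "stop"]
  with_stop <- count_variants(c(stop_key, wl_nnk$dna_sequence[1]), wl_nnk)
  expect_equal(unname(with_stop$counts[["STOP"]]), 1)
  expect_equal(with_stop$discarded, 0)
  no_stop <- count_variants(c(stop_key, wl_nnk$dna_sequence[1]), wl_nnk,
                            include_stops = FALSE)
  expect_false("STOP" %in% names(no_stop$counts))
  expect_equal(no_stop$discarded, 1)
  expect_equal(no_stop$total_mapped + no_stop$discarded, 2)
})

test_that("re-emitted simulated pools are recovered exactly", {
  tr <- screen_truth(wl_nnk, n_reps = 1L, depth = 2000)
  cnt <- simulate_screen_counts(tr, seed = 6L)[[1]]$minus
  reads <- rep(wl_nnk$dna_sequence,
               cnt$counts[wl_nnk$variant_id])
  tab <- count_variants(reads, wl_nnk)
  expect_equal(tab$counts, cnt$counts)
  expect_equal(tab$discarded, 0)
})

test_that("QC gates: depth, inclusive internal-control deviation, parent absence, skew", {
  ids <- unique(wl_nnk$variant_id)
  parent_id <- wl_nnk$variant_id[wl_nnk$class == "parent"]
  ic_ids <- wl_nnk$variant_id[wl_nnk$class == "internal_control"]
  base <- setNames(rep(100, length(ids)), ids)

  # deviation exactly 0.10 passes (boundary inclusive):
  # parent 2000 / 200000, pooled internal control 2200 / 200000
  counts <- base
  counts[parent_id] <- 2000
  counts[ic_ids] <- c(1100, 1100)
  counts[setdiff(ids, c(parent_id, ic_ids))] <-
    (2e5 - 4200) / (length(ids) - 3)
  tab <- variant_count_table(counts, "s", 1L, "GFP_MINUS")
  qc <- qc_sample(tab, wl_nnk)
  expect_equal(qc$ic_deviation, 0.10, tolerance = 1e-12)
  expect_true(qc$pass)

  # deviation just above 0.10 fails
  counts[ic_ids] <- c(1105, 1105)
  qc2 <- qc_sample(variant_count_table(counts, "s", 1L, "GFP_MINUS"), wl_nnk)
  expect_false(qc2$pass)
  expect_true("internal control deviation" %in% qc2$reasons)

  # low depth
  low <- setNames(rep(1000, length(ids)), ids)
  qc3 <- qc_sample(variant_count_table(low, "s", 1L, "GFP_MINUS"), wl_nnk)
  expect_false(qc3$pass)
  expect_true("low depth" %in% qc3$reasons)

  # parent absent: no division attempted, explicit reason
  noparent <- counts
  noparent[parent_id] <- 0
  qc4 <- qc_sample(variant_count_table(noparent, "s", 1L, "GFP_MINUS"),
                   wl_nnk)
  expect_true("parent absent" %in% qc4$reasons)
  expect_true(is.na(qc4$ic_deviation))

  # skew gate: one variant above half of mapped reads
  skewed <- base
  skewed[ids[1]] <- sum(base) * 3
  qc5 <- qc_sample(variant_count_table(skewed, "s", 1L, "GFP_MINUS"),
                   wl_nnk, min_reads = 0)
  expect_true("library skew" %in% qc5$reasons)
})

test_that("fold change follows the normalized-frequency ratio with pseudocounts", {
  mk <- function(counts, pool, rep = 1L)
    variant_count_table(counts, "s", rep, pool)
  plus <- mk(c(v1 = 200, v2 = 800), "GFP_PLUS")
  minus <- mk(c(v1 = 100, v2 = 900), "GFP_MINUS")
  fc <- compute_fold_change(plus, minus, pseudocount = 0)
  expect_equal(fc$fc[fc$variant_id == "v1"], 2.0)

  same <- compute_fold_change(minus, minus, pseudocount = 0)
  expect_true(all(same$fc == 1))

  zero <- compute_fold_change(mk(c(v1 = 0, v2 = 1000), "GFP_PLUS"),
                              minus, pseudocount = 0.5)
  expect_true(all(is.finite(zero$fc)) && all(zero$fc > 0))

  expect_error(compute_fold_change(plus, mk(c(v1 = 1, v2 = 1),
                                            "GFP_MINUS", rep = 2L)),
               "different replicates")
})

test_that("the better-than-parent flag is 'mean over 1 OR every replicate over 1'", {
  mk_fc <- function(id, fcs) do.call(rbind, lapply(seq_along(fcs),
    function(r) data.frame(variant_id = id, fc = fcs[r], replicate = r)))
  tbl <- call_hits(rbind(mk_fc("a", c(1.2, 0.9)),     # mean 1.05 -> flag
                         mk_fc("b", c(1.1, 1.1, 1.1)),# all > 1  -> flag
                         mk_fc("c", c(0.9, 1.05)),    # mean 0.975 -> no
                         mk_fc("d", c(3.0, 0.2))))    # mean 1.6 -> flag
  flags <- setNames(tbl$better_than_parent, tbl$variant_id)
  expect_true(flags[["a"]])
  expect_true(flags[["b"]])
  expect_false(flags[["c"]])
  expect_true(flags[["d"]])
  expect_setequal(tbl$rank, seq_len(nrow(tbl)))
  # ranking: by mean fc descending, ties lexicographic
  tie <- call_hits(rbind(mk_fc("z", c(1.0, 1.0)), mk_fc("y", c(1.0, 1.0)),
                         mk_fc("x", c(2.0, 2.0))))
  expect_identical(tie$variant_id[tie$rank], c("x", "y", "z"))
})

test_that("stop-codon entries are excluded from ranking", {
  tr <- screen_truth(wl_nnk, n_reps = 2L, depth = 1e5)
  cnt <- simulate_screen_counts(tr, seed = 2L)
  hits <- call_hits(lapply(cnt, function(r)
    compute_fold_change(r$plus, r$minus)), wl_nnk)
  expect_false("STOP" %in% hits$variant_id)
  expect_equal(nrow(hits), length(unique(wl_nnk$variant_id)) - 1L)
})

test_that("a 2x enriched variant is recovered within 5% at depth 1e6", {
  ids <- unique(wl_nnk$variant_id)
  enr <- setNames(rep(1, length(ids)), ids)
  enr[["L2W"]] <- 2
  tr <- screen_truth(wl_nnk, enrichment = enr, n_reps = 3L, depth = 1e6)
  cnt <- simulate_screen_counts(tr, seed = 13L)
  hits <- call_hits(lapply(cnt, function(r)
    compute_fold_change(r$plus, r$minus)), wl_nnk)
  rec <- hits$mean_fc[hits$variant_id == "L2W"]
  # with one of 32 entries enriched 2x, renormalisation shifts the
  # expected recovered fold change to 2 / (1 + 1/32)
  expected <- 2 / (1 + 1 / length(ids))
  expect_lt(abs(rec - expected) / expected, 0.05)
})

test_that("null flag rate matches a brute-force multinomial resampler", {
  ids <- paste0("v", 1:20)
  p0 <- rep(1 / 20, 20)
  depth <- 1e4
  n_runs <- 40L
  pipeline_rate <- local({
    wl <- structure(data.frame(dna_sequence = paste0("K", 1:20),
                               variant_id = ids, class = "member",
                               stringsAsFactors = FALSE),
                    class = c("whitelist", "data.frame"))
    flags <- vapply(seq_len(n_runs), function(s) {
      tr <- screen_truth(wl, n_reps = 2L, depth = depth)
      cnt <- simulate_screen_counts(tr, seed = 1000L + s)
      h <- call_hits(lapply(cnt, function(r)
        compute_fold_change(r$plus, r$minus)))
      mean(h$better_than_parent)
    }, numeric(1))
    mean(flags)
  })
  # independent resampler: raw multinomial draws + direct rule arithmetic
  set.seed(77)
  oracle_rate <- mean(vapply(seq_len(n_runs), function(s) {
    fcs <- vapply(1:2, function(r) {
      cp <- drop(rmultinom(1, depth, p0))
      cm <- drop(rmultinom(1, depth, p0))
      fp <- (cp + 0.5) / (depth + 0.5 * 20)
      fm <- (cm + 0.5) / (depth + 0.5 * 20)
      fp / fm
    }, numeric(20))
    mean(rowMeans(fcs) > 1 | apply(fcs > 1, 1, all))
  }, numeric(1)))
  se <- sqrt(oracle_rate * (1 - oracle_rate) / (n_runs * 20)) +
    sqrt(pipeline_rate * (1 - pipeline_rate) / (n_runs * 20))
  expect_lt(abs(pipeline_rate - oracle_rate), 5 * se + 0.02)
})
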