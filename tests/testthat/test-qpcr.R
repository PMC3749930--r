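test_that("relative ratio follows (1+E)^-dCt", {
  r0 <- qpcr_record("s", "a", c(20, 20, 20))
  expect_equal(relative_ratio(r0, qpcr_record("s", "b", 20)), 1)
  expect_equal(relative_ratio(qpcr_record("s", "a", 19),
                              qpcr_record("s", "b", 20)), 2)
  # the printed gln:oriC frequency 0.98 corresponds to dCt = -log2(0.98)
  t <- qpcr_record("s", "gln", 20 - log2(0.98))
  r <- qpcr_record("s", "oriC", 20)
  expect_equal(relative_ratio(t, r), 0.98, tolerance = 1e-12)
  # brute-force check over random records and efficiencies
  withr::with_seed(3, {
    for (k in 1:10) {
      e <- runif(1, 0.8, 1)
      ct1 <- runif(1, 15, 30); ct2 <- runif(1, 15, 30)
      expect_equal(relative_ratio(qpcr_record("s", "a", ct1, e),
                                  qpcr_record("s", "b", ct2, e)),
                   (1 + e)^(-(ct1 - ct2)), tolerance = 1e-12)
    }
  })
  expect_warning(
    relative_ratio(qpcr_record("s", "a", c(20, 20.8)),
                   qpcr_record("s", "b", 20)),
    "spread")
})

test_that("relative ratio is reflexive and multiplicative across references", {
  withr::with_seed(4, {
    recs <- lapply(1:3, function(i)
      qpcr_record("s", paste0("l", i),
                  runif(1, 18, 25) + rnorm(3, 0, 0.1)))
  })
  for (r in recs) expect_equal(relative_ratio(r, r), 1)
  ab <- relative_ratio(recs[[1]], recs[[2]])
  bc <- relative_ratio(recs[[2]], recs[[3]])
  ac <- relative_ratio(recs[[1]], recs[[3]])
  expect_equal(ab * bc, ac, tolerance = 1e-12)
})

test_that("runoff quantification computes the mass-weighted origin mean", {
  h <- runoff_histogram(c(1.0, 2.0), c(0, 100))
  expect_equal(copies_per_cell_from_runoff(h, 1.0)$copies_per_cell, 2.0)
  # 94% of mass at 2 origins, 6% at 1, times the 0.98 gln:oriC ratio
  h <- runoff_histogram(c(1, 2), c(6, 94))
  res <- copies_per_cell_from_runoff(h, 0.98)
  expect_equal(res$origins_per_cell, 1.94)
  expect_equal(res$copies_per_cell, 1.9012, tolerance = 1e-9)
  # mass conservation: assigned + unassigned = total
  h <- runoff_histogram(c(1, 2, 2.8), c(10, 78, 12))
  expect_warning(res <- copies_per_cell_from_runoff(h), "unassigned")
  expect_equal(res$unassigned_fraction, 0.12)
  expect_equal(sum(res$weights), 1)
  expect_error(copies_per_cell_from_runoff(
    runoff_histogram(c(5.5, 5.8), c(50, 50))), "resolvable")
})

test_that("simulated runoff histograms are quantified to the planted truth", {
  h <- simulate_runoff_histogram(c("1" = 0.06, "2" = 0.94), n_cells = 10000,
                                 cv = 0.08, seed = 12)
  expect_equal(sum(h$counts), 10000)
  res <- copies_per_cell_from_runoff(h, 1.0)
  expect_lt(abs(res$origins_per_cell - 1.94), 0.03)
  # sharp single peak at 2 origins
  h2 <- simulate_runoff_histogram(c("2" = 1), n_cells = 5000, cv = 0.01,
                                  seed = 13)
  expect_equal(copies_per_cell_from_runoff(h2)$origins_per_cell, 2,
               tolerance = 1e-3)
})

test_that("standard curves recover quantity and implied efficiency", {
  # perfect doubling: slope -1/log10(2)
  q <- c(0, 1, 2, 3)
  curve <- data.frame(log10_quantity = q, ct = 30 - q / log10(2))
  res <- standard_curve_quantification(curve, sample_ct = 28)
  expect_equal(res$efficiency, 1, tolerance = 1e-9)
  expect_equal(res$quantity, 10^((28 - 30) / res$slope), tolerance = 1e-9)
  # noise-free synthetic curve at E = 0.95 is exact
  e <- 0.95
  curve <- data.frame(log10_quantity = q,
                      ct = 26 - q * log(10) / log(1 + e))
  res <- standard_curve_quantification(curve, sample_ct = 24.2)
  expect_equal(res$efficiency, e, tolerance = 1e-9)
  truth <- (1 + e)^(26 - 24.2)
  expect_equal(res$quantity, truth, tolerance = 1e-9)
  # noisy curve recovers within 5%
  withr::with_seed(14, {
    curve$ct <- curve$ct + rnorm(4, 0, 0.05)
  })
  res <- suppressWarnings(standard_curve_quantification(curve, 24.2))
  expect_lt(abs(res$quantity - truth) / truth, 0.05)
  expect_warning(
    standard_curve_quantification(
      data.frame(log10_quantity = q, ct = 30 - q / log10(2)), 40),
    "extrapolat")
})

test_that("runoff-derived and standard-curve copy numbers agree on matched samples", {
  # same underlying sample: 1.94 origins/cell, gln:oriC 0.98
  h <- simulate_runoff_histogram(c("1" = 0.06, "2" = 0.94), n_cells = 10000,
                                 cv = 0.08, seed = 15)
  via_runoff <- copies_per_cell_from_runoff(h, 0.98)$copies_per_cell
  truth <- 1.94 * 0.98
  q <- seq(-0.5, 1, 0.25)
  curve <- data.frame(log10_quantity = q, ct = 25 - q / log10(2))
  sample_ct <- 25 - log10(truth) / log10(2) + 0.02  # small plate offset
  via_curve <- standard_curve_quantification(curve, sample_ct)$quantity
  expect_lt(abs(via_curve - via_runoff), 0.08)
})

test_that("roadblock ratios near 1 pass and >threshold are flagged", {
  up <- qpcr_record("s", "up", 20)
  down <- qpcr_record("s", "down", 20)
  res <- roadblock_ratio(up, down)
  expect_equal(res$ratio, 1)
  expect_false(res$flagged)
  up3 <- qpcr_record("s", "up", 20 - log2(3))
  res <- roadblock_ratio(up3, down)
  expect_equal(res$ratio, 3, tolerance = 1e-12)
  expect_true(res$flagged)
  # planted 2x paused-fork sample
  tab <- simulate_qpcr(c(up = 2, down = 1), ct_sd = 0.05, seed = 16)
  res <- roadblock_ratio(ct_table_record(tab, "up"),
                         ct_table_record(tab, "down"))
  expect_lt(abs(res$ratio - 2), 0.1)
  expect_true(res$flagged)
})

test_that("ChIP fold enrichment self-normalizes and exponentiates ddCt", {
  s <- data.frame(locus = c("dnaB", "gln", "oriC"),
                  ct_ip = c(28, 28 - log2(10), 28 - log2(25)),
                  ct_input = c(20, 20, 20))
  res <- chip_fold_enrichment(s, "dnaB")
  expect_equal(res$fold[res$locus == "dnaB"], 1)
  expect_equal(res$fold[res$locus == "gln"], 10, tolerance = 1e-9)
  expect_equal(res$fold[res$locus == "oriC"], 25, tolerance = 1e-9)
  expect_error(chip_fold_enrichment(s, "lac"), "reference")
})

test_that("fold enrichment is invariant to a constant added to all Cts", {
  tab <- simulate_chip_qpcr(c(dnaB = 1, lac = 1.2, gln = 10, oriC = 25),
                            seed = 17)
  base <- chip_fold_enrichment(tab, "dnaB")
  shifted <- tab
  shifted$ct_ip <- shifted$ct_ip + 3.7
  shifted$ct_input <- shifted$ct_input + 3.7
  expect_equal(chip_fold_enrichment(shifted, "dnaB")$fold, base$fold,
               tolerance = 1e-12)
  # planted folds recovered within 10%
  truth <- c(dnaB = 1, gln = 10, lac = 1.2, oriC = 25)  # alphabetical
  expect_true(all(abs(base$fold - truth[base$locus]) / truth[base$locus]
                  < 0.10))
})
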