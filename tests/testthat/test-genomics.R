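test_that("motif positions are found linearly and across the junction", {
  expect_equal(as.integer(motif_positions("GATCGATC", circular = FALSE)),
               c(1L, 5L))
  # circular "ATCG": G at 4 wraps with ATC at 1-3
  expect_equal(as.integer(motif_positions("ATCG", circular = TRUE)), 4L)
  expect_equal(length(motif_positions("ATCG", circular = FALSE)), 0L)
  # ambiguous bases are skipped and tallied
  hits <- motif_positions("GANCGATC", circular = FALSE)
  expect_equal(as.integer(hits), 5L)
  expect_equal(attr(hits, "ambiguous_skipped"), 1L)
})

test_that("motif scan matches the naive oracle on random circular sequences", {
  withr::with_seed(41, {
    for (k in 1:5) {
      s <- random_seq(3000)
      expect_equal(as.integer(motif_positions(s, "GATC", circular = TRUE)),
                   oracle_motif_scan(s, "GATC", circular = TRUE))
    }
  })
})

test_that("GATC counts are strand-symmetric and near the binomial expectation", {
  withr::with_seed(42, {
    s <- random_seq(1e6)
  })
  n_fwd <- length(motif_positions(s, "GATC", circular = TRUE))
  n_rev <- length(motif_positions(rc(s), "GATC", circular = TRUE))
  expect_equal(n_fwd, n_rev)
  # expectation L/4^4 with binomial-scale spread
  expected <- 1e6 / 256
  expect_lt(abs(n_fwd - expected), 3 * sqrt(expected))
})

test_that("window density conserves total counts and matches a recount", {
  # uniform positions every 250 bp: constant 4 per kb
  pos <- seq(1, 10000, 250)
  tr <- window_density(pos, 10000, 1000)
  expect_true(all(tr$value == 4))
  expect_equal(sum(attr(tr, "counts")), length(pos))
  # empty positions: all-zero track
  tr0 <- window_density(integer(0), 10000, 1000)
  expect_true(all(tr0$value == 0))
  # random positions: per-window counts equal a brute-force recount
  withr::with_seed(43, {
    pos <- sort(sample.int(50000, 800))
  })
  tr <- window_density(pos, 50000, 1000)
  counts <- attr(tr, "counts")
  brute <- sapply(seq(1, 50000, 1000), function(s)
    sum(pos >= s & pos <= s + 999))
  expect_equal(counts, brute)
  expect_equal(sum(counts), 800)
  expect_error(window_density(pos, 50000, 60000), "larger than the genome")
})

test_that("moving average is exact against the naive circular oracle", {
  # constant track unchanged
  pos <- seq(500, 100000, 500)
  tr <- genome_track(pos, rep(2.5, length(pos)), 100000)
  expect_equal(moving_average(tr, 5000)$value, rep(2.5, length(pos)))
  # unit impulse spreads to 1/k over the k probes in the window
  v <- rep(0, length(pos)); v[100] <- 1
  sm <- moving_average(genome_track(pos, v, 100000), 5000)
  k <- sum(sm$value > 0)
  expect_equal(sort(unique(sm$value[sm$value > 0])), 1 / 11)
  expect_equal(k, 11)
  # random track vs O(n*w) oracle
  withr::with_seed(44, {
    v <- rnorm(length(pos))
  })
  tr <- genome_track(pos, v, 100000)
  for (w in c(5000, 40000)) {
    expect_equal(moving_average(tr, w)$value,
                 oracle_circular_window_mean(pos, v, 100000, w),
                 tolerance = 1e-12)
  }
  # mean preservation on evenly spaced probes
  expect_equal(mean(moving_average(tr, 40000)$value), mean(v),
               tolerance = 1e-12)
})

test_that("tracks and correlations are invariant under genome rotation", {
  withr::with_seed(45, {
    g <- simulate_genome(genome_length = 50000, probe_spacing = 500,
                         snap_windows = data.frame(start = 10001,
                                                   end = 18000),
                         snap_multiplier = 4, n_loci = 8, seed = 99)
  })
  L <- 50000
  rot <- 12345
  s2 <- paste0(substr(g$sequence, rot + 1, L), substr(g$sequence, 1, rot))
  n1 <- length(motif_positions(g$sequence))
  n2 <- length(motif_positions(s2))
  expect_equal(n1, n2)
  d1 <- window_density(motif_positions(g$sequence), L, 500)
  d2 <- window_density(motif_positions(s2), L, 500)
  expect_equal(sum(attr(d1, "counts")), sum(attr(d2, "counts")))
})

test_that("cohesion-binding correlation hits the monotone extremes", {
  pos <- seq(1000, 100000, 1000)
  tr <- genome_track(pos, seq_along(pos), 100000)
  loci <- data.frame(name = letters[1:5],
                     position = c(5000, 20000, 40000, 60000, 90000),
                     cohesion_minutes = c(1, 2, 3, 4, 5))
  expect_equal(cohesion_binding_correlation(loci, tr)$rho, 1)
  loci$cohesion_minutes <- rev(loci$cohesion_minutes)
  expect_equal(cohesion_binding_correlation(loci, tr)$rho, -1)
  loci$cohesion_minutes <- rep(3, 5)
  expect_error(cohesion_binding_correlation(loci, tr), "tied")
  expect_error(cohesion_binding_correlation(loci[1:3, ], tr), "4")
})

test_that("planted 5-kb cohesion signal correlates better at 5 kb than 40 kb", {
  for (s in 1:10) {
    g <- simulate_genome(genome_length = 120000, gatc_rate = 1 / 256,
                         snap_windows = data.frame(
                           start = c(20001, 80001), end = c(28000, 88000)),
                         snap_multiplier = 5, probe_spacing = 500,
                         n_loci = 12, seed = s)
    dens <- window_density(g$gatc_positions, 120000, 500)
    rho5 <- cohesion_binding_correlation(g$loci,
                                         moving_average(dens, 5000))$rho
    rho40 <- cohesion_binding_correlation(g$loci,
                                          moving_average(dens, 40000))$rho
    expect_gte(rho5, rho40)
    expect_gte(rho5, 0.9)
  }
})

test_that("snap windows show the planted density contrast", {
  g <- simulate_genome(genome_length = 200000, gatc_rate = 1 / 256,
                       snap_windows = data.frame(start = 50001, end = 150000),
                       snap_multiplier = 3, seed = 7)
  pos <- as.integer(g$gatc_positions)
  in_snap <- pos > 50000 & pos <= 150000
  dens_snap <- sum(in_snap) / 100000
  dens_bg <- sum(!in_snap) / 100000
  expect_equal(dens_snap / dens_bg, 3, tolerance = 0.25)
  # null case: multiplier 1 gives statistically indistinguishable halves
  pvals <- sapply(1:10, function(s) {
    g0 <- simulate_genome(genome_length = 60000, gatc_rate = 1 / 256,
                          snap_windows = data.frame(start = 1, end = 30000),
                          snap_multiplier = 1, seed = s + 500)
    p <- as.integer(g0$gatc_positions)
    m <- matrix(c(sum(p <= 30000), sum(p > 30000), 30000, 30000), 2)
    suppressWarnings(chisq.test(m)$p.value)
  })
  expect_gt(mean(pvals > 0.05), 0.7)
})
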