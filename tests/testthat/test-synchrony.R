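test_that("cumulative curves normalize monotone signals to 0-100%", {
  t <- seq(0, 60, 10)
  # noise-free step from 1.0 to 1.8 at t = 40
  s <- c(1, 1, 1, 1, 1.8, 1.8, 1.8)
  cc <- cumulative_curve(t, s)
  expect_equal(cc$cumulative, c(0, 0, 0, 0, 100, 100, 100))
  # noise-free linear ramp over [20, 60]
  t <- seq(0, 80, 5)
  s <- approx(c(0, 20, 60, 80), c(1, 1, 1.8, 1.8), xout = t)$y
  cc <- cumulative_curve(t, s)
  ramp <- t >= 20 & t <= 60
  expect_equal(cc$cumulative[ramp], (t[ramp] - 20) / 40 * 100)
  expect_equal(crossing_time(cc), 40)
  expect_error(cumulative_curve(seq(0, 30, 10), rep(1, 4)), "5 time points")
})

test_that("flat noisy signals are rejected as below the noise floor", {
  withr::with_seed(18, {
    t <- seq(0, 120, 10)
    s <- 1 + rnorm(length(t), 0, 0.03)
  })
  expect_error(cumulative_curve(t, s), "noise floor")
})

test_that("crossing times interpolate between bracketing samples", {
  cc <- data.frame(time = c(30, 40), cumulative = c(40, 60))
  expect_equal(crossing_time(cc, 50), 35)
  # step curve: crossing inside the jump interval
  cc <- data.frame(time = seq(0, 60, 10),
                   cumulative = c(0, 0, 0, 0, 100, 100, 100))
  ct <- crossing_time(cc, 50)
  expect_gte(ct, 30)
  expect_lte(ct, 40)
  expect_error(crossing_time(data.frame(time = 1:5,
                                        cumulative = c(0, 10, 20, 30, 40))),
               "never reaches")
})

test_that("synthetic curves track the generator truth CDF within 5 points", {
  p <- cell_cycle_params(119, 8.8, 31)
  tc <- simulate_synchronized_timecourse(p, seq(0, 120, 10), 2000,
                                         synchrony_fraction = 0.8,
                                         event_sd = 5, seed = 19)
  cc <- cumulative_curve(tc$time_min, tc$mean_copy_number)
  # truth: synchronous-fraction replication CDF normalized like the curve
  truth_s <- function(t) 0.8 * pnorm(t, 8.8, 5) + 0.2 * t / 119
  tt <- tc$time_min
  truth_cum <- 100 * (truth_s(tt) - truth_s(0)) /
    (truth_s(max(tt)) - truth_s(0))
  expect_lt(max(abs(cc$cumulative - truth_cum)), 5)
})

test_that("t50 recovery on noisy curves is within half the sampling interval", {
  p <- cell_cycle_params(119, 30, 31)
  errs <- sapply(1:50, function(s) {
    tc <- simulate_synchronized_timecourse(p, seq(0, 120, 10), 1000,
                                           seed = s)
    cc <- cumulative_curve(tc$time_min, tc$mean_copy_number)
    crossing_time(cc) - 30
  })
  expect_lt(abs(mean(errs)), 5)
})

test_that("cohesion period is the interval between the two 50% crossings", {
  t <- seq(0, 120, 10)
  s <- 1 + 0.8 * pnorm(t, 40, 5)
  rep_c <- cumulative_curve(t, s)
  expect_equal(cohesion_period(rep_c, rep_c)$cohesion_period, 0)
  seg_c <- cumulative_curve(t, 1 + 0.8 * pnorm(t, 70, 5))
  res <- cohesion_period(rep_c, seg_c)
  expect_equal(res$cohesion_period, 30, tolerance = 0.2)
  expect_false(res$negative_flag)
  expect_warning(res <- cohesion_period(seg_c, rep_c), "negative")
  expect_true(res$negative_flag)
})

test_that("perfect synchrony with no event spread recovers cohesion exactly", {
  p <- cell_cycle_params(119, 20, 30)
  tc <- simulate_synchronized_timecourse(p, seq(0, 120, 5), 500,
                                         synchrony_fraction = 1,
                                         event_sd = 0, seed = 20)
  res <- cohesion_period(cumulative_curve(tc$time_min, tc$mean_copy_number),
                         cumulative_curve(tc$time_min, tc$mean_foci))
  expect_equal(res$cohesion_period, 30, tolerance = 2.6)
  # plateau/baseline doubling at full synchrony
  cc <- cumulative_curve(tc$time_min, tc$mean_copy_number)
  expect_equal(attr(cc, "plateau") / attr(cc, "baseline"), 2)
})

test_that("cohesion recovery over the condition grid has small bias and SD", {
  for (delta in c(5, 10, 20, 30, 60)) {
    for (phi in c(0.75, 0.85)) {
      p <- cell_cycle_params(150, 25, delta)
      rec <- sapply(1:3, function(s) {
        tc <- simulate_synchronized_timecourse(
          p, seq(0, 130, 10), 1000, synchrony_fraction = phi, seed = s)
        cohesion_period(
          cumulative_curve(tc$time_min, tc$mean_copy_number),
          cumulative_curve(tc$time_min, tc$mean_foci))$cohesion_period
      })
      expect_lt(abs(mean(rec) - delta), 2)
      expect_lt(sd(rec), 3)
    }
  }
})

test_that("translating both curves translates crossings and not the period", {
  t <- seq(0, 120, 10)
  rep_c <- cumulative_curve(t, 1 + 0.8 * pnorm(t, 30, 5))
  seg_c <- cumulative_curve(t, 1 + 0.8 * pnorm(t, 55, 5))
  base <- cohesion_period(rep_c, seg_c)
  shift <- 15
  rep_s <- rep_c; rep_s$time <- rep_s$time + shift
  seg_s <- seg_c; seg_s$time <- seg_s$time + shift
  shifted <- cohesion_period(rep_s, seg_s)
  expect_equal(shifted$t50_replication, base$t50_replication + shift,
               tolerance = 1e-9)
  expect_equal(shifted$cohesion_period, base$cohesion_period,
               tolerance = 1e-9)
})

test_that("cumulative curves end at 100% regardless of synchrony fraction", {
  p <- cell_cycle_params(119, 20, 30)
  for (phi in c(0.75, 1)) {
    tc <- simulate_synchronized_timecourse(p, seq(0, 120, 10), 1000,
                                           synchrony_fraction = phi,
                                           seed = 22)
    cc <- cumulative_curve(tc$time_min, tc$mean_copy_number)
    expect_equal(cc$cumulative[1], 0)
    expect_equal(cc$cumulative[nrow(cc)], 100)
  }
})

test_that("B, C, D periods follow their definitions and sum to tau", {
  t <- seq(0, 120, 10)
  oric <- cumulative_curve(t, 1 + 0.8 * pnorm(t, 10, 3))
  ter <- cumulative_curve(t, 1 + 0.8 * pnorm(t, 70, 3))
  per <- cell_cycle_periods(oric, ter, 119)
  expect_equal(unname(sum(per)), 119)
  expect_equal(unname(per["B"]), 10, tolerance = 0.5)
  expect_equal(unname(per["C"]), 60, tolerance = 1)
  expect_error(cell_cycle_periods(ter, oric, 119), "precedes")
  # injected B/C/D recovered within 2 min from simulated curves
  tau <- 119
  p_ori <- cell_cycle_params(tau, 12, 0)
  p_ter <- cell_cycle_params(tau, 75, 0)
  tc_o <- simulate_synchronized_timecourse(p_ori, seq(0, 110, 10), 1000,
                                           seed = 23)
  tc_t <- simulate_synchronized_timecourse(p_ter, seq(0, 110, 10), 1000,
                                           seed = 24)
  per <- cell_cycle_periods(
    cumulative_curve(tc_o$time_min, tc_o$mean_copy_number),
    cumulative_curve(tc_t$time_min, tc_t$mean_copy_number), tau)
  expect_lt(abs(per["B"] - 12), 2)
  expect_lt(abs(per["C"] - 63), 2)
  expect_lt(abs(per["D"] - 44), 2)
})
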