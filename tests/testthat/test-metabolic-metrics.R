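test_that("SMR is the mean of the lowest decile with deterministic counting", {
  s <- make_series(1:20, c(30, 32, seq(40, 91, by = 3)))
  expect_equal(compute_smr(s), 31) # lowest ceil(0.1 * 20) = 2 values: 30, 32

  s_const <- make_series(1:12, rep(55, 12))
  expect_equal(compute_smr(s_const), 55)

  expect_error(compute_smr(make_series(1:5, 1:5)), "at least 10")
})

test_that("MMR is the single highest accepted value", {
  expect_equal(compute_mmr(make_series(1:3, c(45, 110, 80))), 110)
  expect_equal(compute_mmr(make_series(1, 77)), 77)
  # rejected cycles cannot set MMR
  s <- make_series(1:3, c(45, 300, 80), accepted = c(TRUE, FALSE, TRUE))
  expect_equal(compute_mmr(s), 80)
})

test_that("RMR is the post-window mean with its SD", {
  s <- make_series(c(1, 5, 17, 20, 23), c(100, 80, 50, 52, 48))
  fit <- compute_rmr(s, window_start = 16)
  expect_equal(fit$rmr, 50)
  expect_equal(fit$rmr_sd, 2)
  expect_error(compute_rmr(make_series(1:5, 1:5), 16), "after 16")
})

test_that("recovery time is the third sub-threshold cycle", {
  mo2 <- c(100, 90, 60, 55, 58, 52)
  s <- make_series(1:6, mo2)
  # theta = 59: sub-threshold at t = 4, 5(58<59), 6 -> third at 6 h
  expect_equal(compute_recovery_time(s, rmr = 58, rmr_sd = 1), 6)
  expect_equal(recovery_time_oracle(1:6, mo2, 59), 6)

  # threshold above everything: recovery at the third cycle
  expect_equal(compute_recovery_time(s, rmr = 200, rmr_sd = 0), 3)

  # monotone decreasing series: cumulative and consecutive rules agree
  s_mono <- make_series(1:8, seq(100, 30, by = -10))
  expect_equal(
    compute_recovery_time(s_mono, 60, 1),
    compute_recovery_time(s_mono, 60, 1, rule = "consecutive")
  )

  expect_warning(
    rt <- compute_recovery_time(make_series(1:4, c(10, 1, 10, 10)), rmr = 2, rmr_sd = 0),
    "not recovered"
  )
  expect_true(is.na(rt))
})

test_that("recovery-time rules match brute-force scans on random series", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    times <- sort(runif(n, 0, 48))
    vals <- runif(n, 20, 120)
    thr <- runif(1, 20, 120)
    s <- make_series(times, vals)
    got <- suppressWarnings(compute_recovery_time(s, thr, 0))
    expect_identical(got, recovery_time_oracle(times, vals, thr))
  }
})

test_that("EPOC is the clipped trapezoidal excess up to recovery", {
  # triangle: (0 h, 110) to (2 h, 50) above rmr = 50 -> area 60
  s <- make_series(c(0, 2), c(110, 50))
  expect_equal(compute_epoc(s, 2, baseline_mode = "rmr", rmr = 50), 60)

  # constant at rmr: zero excess
  s0 <- make_series(0:5, rep(40, 6))
  expect_equal(compute_epoc(s0, 5, baseline_mode = "rmr", rmr = 40), 0)

  # dips below baseline contribute zero, not negative, area
  s1 <- make_series(0:2, c(60, 20, 60))
  expect_equal(compute_epoc(s1, 2, baseline_mode = "rmr", rmr = 40), 20)

  # baseline modes: none integrates the literal area under the curve
  s2 <- make_series(c(0, 1), c(100, 60))
  expect_equal(compute_epoc(s2, 1, baseline_mode = "none"), 80)
  expect_equal(compute_epoc(s2, 1, baseline_mode = "smr", smr = 30), 50)

  expect_error(compute_epoc(s2, NA), "undefined")
})

test_that("EPOC is monotone non-decreasing in recovery time", {
  set.seed(3)
  times <- c(0, 1, sort(runif(28, 2, 24)))
  s <- make_series(times, 50 + 60 * exp(-times / 3) + rnorm(30, 0, 2))
  cuts <- seq(2, 24, by = 2)
  vals <- vapply(
    cuts, function(ct) compute_epoc(s, ct, baseline_mode = "rmr", rmr = 50),
    numeric(1)
  )
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("recovery rate times recovery time returns EPOC exactly", {
  expect_equal(compute_recovery_rate(180, 6), 30)
  expect_equal(compute_recovery_rate(0, 6), 0)
  expect_error(compute_recovery_rate(100, NA), "positive")
  set.seed(9)
  for (i in 1:20) {
    epoc <- runif(1, 0, 500)
    rt <- runif(1, 1, 20)
    expect_equal(compute_recovery_rate(epoc, rt) * rt, epoc)
  }
})

test_that("the trial summary preserves trait identities and orderings", {
  truth <- simulation_truth(seed = 21)
  ch <- chamber_spec(trial_duration = 30)
  traj <- simulate_mo2_trajectory(truth, 30)
  tr <- synthesize_trace(traj, ch, truth)
  bg <- truth$background_fraction * truth$smr_true * ch$body_mass
  ser <- extract_mo2(tr, ch, background = bg)
  ms <- metabolic_summary(ser)

  expect_true(ms$qc_ordering_ok)
  expect_equal(ms$aerobic_scope, ms$mmr - ms$smr)
  expect_equal(ms$factorial_scope, ms$mmr / ms$smr)
  expect_gte(ms$factorial_scope, 1)
  expect_equal(ms$recovery_rate * ms$recovery_time, ms$epoc)
  expect_identical(ms$baseline_mode, "rmr")
  expect_identical(ms$recovery_rule, "cumulative")

  # glance() on the series is the same summary; tidy() is the cycle table
  expect_equal(glance(ser), ms)
  expect_identical(nrow(tidy(ser)), nrow(ser))
})

test_that("simulated trials recover the generating parameters", {
  ch <- chamber_spec(trial_duration = 48)
  errs <- purrr::map_dfr(1:6, function(i) {
    truth <- simulation_truth(seed = 100 + i)
    traj <- simulate_mo2_trajectory(truth, 48)
    tr <- synthesize_trace(traj, ch, truth)
    bg <- truth$background_fraction * truth$smr_true * ch$body_mass
    ser <- extract_mo2(tr, ch, background = bg)
    ms <- metabolic_summary(ser)
    tibble::tibble(
      smr = abs(ms$smr - truth$smr_true) / truth$smr_true,
      mmr = abs(ms$mmr - truth$mmr_true) / truth$mmr_true,
      rmr = abs(ms$rmr - truth$rmr_true) / truth$rmr_true,
      epoc = abs(ms$epoc - truth$epoc_true) / truth$epoc_true
    )
  })
  expect_lt(median(errs$smr), 0.05)
  expect_lt(median(errs$mmr), 0.05)
  expect_lt(median(errs$rmr), 0.05)
  expect_lt(median(errs$epoc), 0.10)
})
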