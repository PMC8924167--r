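test_that("cycle slope fitting is exact on a line and flags constants", {
  t_s <- seq(0, 360, by = 10)
  o2 <- 8 - 0.5 * t_s / 360 # 0.5 mg/L over 0.1 h
  fit <- fit_cycle_slope(t_s, o2)
  expect_equal(fit$slope, -5, tolerance = 1e-10)
  expect_equal(fit$r2, 1)

  flat <- fit_cycle_slope(t_s, rep(8, length(t_s)))
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$r2))

  expect_error(fit_cycle_slope(c(0, 10), c(8, 7.9)), "at least 3 samples")
})

test_that("noisy seeded cycles recover the generating slope", {
  set.seed(42)
  t_s <- seq(0, 350, by = 10)
  errs <- replicate(200, {
    o2 <- 8 - 5 * t_s / 3600 + rnorm(length(t_s), 0, 0.01)
    fit_cycle_slope(t_s, o2)$slope - (-5)
  })
  # OLS standard error for this design is ~0.058 mg/L/h
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(sd(errs), 0.1)
})

test_that("slope-to-MO2 conversion applies volume, background and mass", {
  ch <- chamber_spec(chamber_volume = 10, body_volume = 1, body_mass = 1)
  expect_equal(mo2_from_slope(-5, ch), 45)
  expect_equal(mo2_from_slope(-5, ch, background_rate = 2.25), 42.75)

  # body volume via the default density: 1.12 kg at 1.12 g/mL displaces 1 L
  ch2 <- chamber_spec(chamber_volume = 10, body_mass = 1.12, body_density = 1.12)
  expect_equal(ch2$effective_volume, 9)

  expect_error(chamber_spec(chamber_volume = 1, body_volume = 2), "Effective volume")
})

test_that("MO2 conversion is bilinear in slope and effective volume", {
  set.seed(1)
  for (i in 1:25) {
    slope <- -runif(1, 1, 10)
    v <- runif(1, 5, 12)
    mass <- runif(1, 0.5, 2)
    ch <- chamber_spec(chamber_volume = v + 1, body_volume = 1, body_mass = mass)
    ch2 <- chamber_spec(chamber_volume = 2 * v + 1, body_volume = 1, body_mass = mass)
    base <- mo2_from_slope(slope, ch)
    expect_equal(mo2_from_slope(2 * slope, ch), 2 * base)
    expect_equal(mo2_from_slope(slope / 2, ch2), base)
  }
})

test_that("background correction interpolates linearly with documented fallback", {
  f <- background_correction(list(pre_rate = 2, post_rate = 2), 48)
  expect_equal(f(c(0, 24, 48)), c(2, 2, 2))
  g <- background_correction(list(pre_rate = 0, post_rate = 4), 48)
  expect_equal(g(24), 2)
  expect_warning(
    h <- background_correction(list(pre_rate = 3, post_rate = NA), 48),
    "post_rate missing"
  )
  expect_equal(h(c(0, 48)), c(3, 3))
  expect_error(
    background_correction(list(pre_rate = -1, post_rate = 0), 48),
    "non-negative"
  )
})

test_that("saturation QC flags cycles below the floor", {
  tr <- tibble::tibble(
    time_s = c(0, 10, 20, 840, 850, 860),
    o2 = c(8, 7, 6.4, 8, 6, 5.6), # cycle 1 min 80%, cycle 2 min 70%
    phase = "measure",
    cycle = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
  qc <- qc_saturation(tr, saturation_concentration = 8, floor_percent = 77)
  expect_identical(qc$saturation_flag, c(FALSE, TRUE))

  truth <- simulation_truth(noise_sd = 0, activity_burst_rate = 0, quiescent_fraction = 0)
  ch <- chamber_spec(trial_duration = 2)
  traj <- simulate_mo2_trajectory(truth, 2, quiescence = FALSE, bursts = FALSE)
  qc2 <- qc_saturation(synthesize_trace(traj, ch, truth), ch$saturation_concentration)
  expect_false(any(qc2$saturation_flag))
})

test_that("extraction matches generator MO2 on a noise-free trace", {
  truth <- simulation_truth(
    noise_sd = 0, activity_burst_rate = 0, quiescent_fraction = 0,
    background_fraction = 0.05
  )
  ch <- chamber_spec(trial_duration = 12)
  traj <- simulate_mo2_trajectory(truth, 12, quiescence = FALSE, bursts = FALSE)
  tr <- synthesize_trace(traj, ch, truth)
  bg <- truth$background_fraction * truth$smr_true * ch$body_mass
  ser <- extract_mo2(tr, ch, background = bg)
  true_at <- approx(traj$time_h, traj$mo2, xout = ser$cycle_time_h)$y
  # discretisation error is O(cycle length); the 6-min average vs midpoint
  rel_err <- abs(ser$mo2 - true_at) / true_at
  expect_lt(max(rel_err), 0.02)
  expect_true(all(ser$accepted))
  expect_true(all(ser$r2 > 0.999))
})

test_that("negative corrected MO2 is flagged, not clipped", {
  tr <- tibble::tibble(
    time_s = c(0, 10, 20, 30),
    o2 = c(8, 8.001, 8.002, 8.003), # rising oxygen: negative uptake
    phase = "measure",
    cycle = 1L
  )
  ch <- chamber_spec(chamber_volume = 10, body_volume = 1, body_mass = 1)
  ser <- extract_mo2(tr, ch, r2_threshold = 0.5)
  expect_lt(ser$mo2, 0)
  expect_true(ser$flag_negative)
  expect_false(ser$accepted)
})
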