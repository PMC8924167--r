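test_that("recovery trajectory starts at MMR and carries the analytic EPOC", {
  truth <- simulation_truth(
    smr_true = 45, rmr_true = 50, mmr_true = 110, tau_recovery = 3
  )
  expect_equal(truth$epoc_true, 180) # (110 - 50) * 3

  traj <- simulate_mo2_trajectory(truth,
    duration = 30, step = 0.01,
    quiescence = FALSE, bursts = FALSE
  )
  expect_equal(traj$mo2[1], 110)
  # closed form at t = tau: rmr + (mmr - rmr)/e
  at_tau <- traj$mo2[which.min(abs(traj$time_h - 3))]
  expect_equal(at_tau, 50 + 60 / exp(1), tolerance = 1e-6)
  # numerical integral of the excess approaches the analytic EPOC
  excess <- traj$mo2 - 50
  integral <- sum(diff(traj$time_h) * (head(excess, -1) + tail(excess, -1)) / 2)
  expect_equal(integral, 180 * (1 - exp(-10)), tolerance = 1e-3)
})

test_that("trajectory rejects non-positive step and tau", {
  truth <- simulation_truth()
  expect_error(simulate_mo2_trajectory(truth, 10, step = 0), "step")
  expect_error(simulation_truth(tau_recovery = -1), "tau_recovery")
})

test_that("quiescent episodes dip to SMR only after the onset time", {
  truth <- simulation_truth(seed = 7)
  traj <- simulate_mo2_trajectory(truth, duration = 40, bursts = FALSE)
  q <- traj[traj$state == "quiescent", ]
  expect_gt(nrow(q), 0)
  expect_true(all(q$time_h >= truth$quiescence_onset))
  late_q <- q[q$time_h > 30, ]
  expect_true(all(abs(late_q$mo2 - truth$smr_true) < 0.5))
})

test_that("sealed-phase decline matches the mass-balance arithmetic", {
  # constant MO2 = 45 mg/h/kg, 1 kg, V_eff = 9 L, 6 min measure:
  # in-cycle drop = 45 * 1 * 0.1 / 9 = 0.5 mg/L
  truth <- simulation_truth(
    smr_true = 45, rmr_true = 45.0001, mmr_true = 45.001,
    tau_recovery = 1e-6, background_fraction = 0, noise_sd = 0,
    activity_burst_rate = 0, quiescent_fraction = 0
  )
  ch <- chamber_spec(
    chamber_volume = 10, body_volume = 1, body_mass = 1, trial_duration = 2
  )
  traj <- tibble::tibble(time_h = c(0, 2), mo2 = c(45, 45), state = "routine")
  tr <- synthesize_trace(traj, ch, truth)
  m1 <- tr[tr$phase == "measure" & tr$cycle == 1, ]
  drop_rate <- (m1$o2[1] - m1$o2[nrow(m1)]) / (m1$time_s[nrow(m1)] - m1$time_s[1])
  expect_equal(drop_rate * 360, 0.5, tolerance = 1e-10)
})

test_that("null metabolism gives flat measure phases at the flush endpoint", {
  truth <- simulation_truth(
    smr_true = 0, rmr_true = 0, mmr_true = 1e-9, tau_recovery = 1,
    background_fraction = 0, noise_sd = 0,
    activity_burst_rate = 0, quiescent_fraction = 0
  )
  ch <- chamber_spec(trial_duration = 1)
  traj <- tibble::tibble(time_h = c(0, 1), mo2 = c(0, 0), state = "routine")
  tr <- synthesize_trace(traj, ch, truth)
  m2 <- tr[tr$phase == "measure" & tr$cycle == 2, ]
  expect_lt(diff(range(m2$o2)), 1e-9)
  expect_equal(m2$o2[1], ch$saturation_concentration, tolerance = 0.06)
})

test_that("same seed gives bit-identical traces; concentrations stay physical", {
  truth <- simulation_truth(seed = 11)
  ch <- chamber_spec(trial_duration = 6)
  traj <- simulate_mo2_trajectory(truth, duration = 6)
  tr1 <- synthesize_trace(traj, ch, truth)
  tr2 <- synthesize_trace(traj, ch, truth)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$o2 > 0))
  expect_true(all(tr1$o2 <= ch$saturation_concentration))
})

test_that("implausibly fast drawdown is rejected with the offending cycle", {
  truth <- simulation_truth(
    smr_true = 4000, rmr_true = 5000, mmr_true = 9000, tau_recovery = 3,
    noise_sd = 0, background_fraction = 0
  )
  ch <- chamber_spec(trial_duration = 1)
  traj <- tibble::tibble(time_h = c(0, 1), mo2 = c(9000, 9000), state = "routine")
  expect_error(synthesize_trace(traj, ch, truth), "cycle 1")
})

test_that("chase tracks encode the true speed exactly", {
  # unit calibration: 24 cm/s at 24 fps and 1 px/cm moves 1 px per frame
  trk <- simulate_chase_track(24, n_flips = 5, fps = 24, px_per_cm = 1, seed = 3)
  ev <- escape_speeds(trk, fps = 24, px_per_cm = 1)
  expect_equal(ev$distance_px / ev$frame_gap, rep(1, 5))

  empty <- simulate_chase_track(24, n_flips = 0, fps = 24, px_per_cm = 1)
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(escape_speeds(empty, px_per_cm = 1)), 0L)

  expect_error(simulate_chase_track(24, 3, fps = 0), "fps")
})

test_that("cohort scaling follows the Q10 relation and the design counts", {
  base <- simulation_truth(smr_true = 30, rmr_true = 36, seed = 5)
  des <- cohort_design(
    n_per_cell = 6, between_animal_cv = 0,
    q10_map = list(smr = 3.3, mmr = 1.4)
  )
  coh <- simulate_cohort(des, base,
    include_traces = FALSE, include_tracks = FALSE
  )
  expect_identical(nrow(coh$animals), 108L) # 6 per cell over 3 x 3 x 2

  cold <- coh$animals[coh$animals$acclimation_temp == 14, ]
  a14 <- cold$smr_true[cold$experimental_temp == 14][1]
  a215 <- cold$smr_true[cold$experimental_temp == 21.5][1]
  expect_equal(a215 / a14, 3.3^0.75, tolerance = 1e-10)
  expect_equal(30 * 3.3^0.75, 73.2, tolerance = 0.01)

  # null plasticity: acclimation factor 1 leaves trait means equal
  des0 <- cohort_design(
    n_per_cell = 2, between_animal_cv = 0,
    acclimation_effect_smr = 1, acclimation_effect_tau = 1
  )
  coh0 <- simulate_cohort(des0, base,
    include_traces = FALSE, include_tracks = FALSE
  )
  by_acc <- tapply(
    coh0$animals$smr_true[coh0$animals$experimental_temp == 14],
    coh0$animals$acclimation_temp[coh0$animals$experimental_temp == 14],
    mean
  )
  expect_equal(max(by_acc) - min(by_acc), 0, tolerance = 1e-10)

  # every record keeps the analytic EPOC identity
  expect_equal(
    coh$animals$epoc_true,
    (coh$animals$mmr_true - coh$animals$rmr_true) * coh$animals$tau_recovery
  )
})
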