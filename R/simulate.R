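# Synthetic respirometry trials with known ground truth.
#
# The generator produces the three linked artefacts a real exhaustion trial
# yields -- a post-exercise oxygen-consumption trajectory, the raw chamber
# oxygen trace recorded by an intermittent-flow respirometer, and a chase
# click track -- together with the parameters that generated them, so the
# whole extraction pipeline can be checked by parameter recovery.

#' Ground-truth parameter set for a simulated trial
#'
#' Bundles the "true" metabolic phenotype of one simulated animal. The
#' post-exercise oxygen consumption model is
#' \deqn{MO_2(t) = b(t) + (MMR - RMR) e^{-t/\tau}}
#' where the baseline \eqn{b(t)} is routine metabolic rate (RMR) interrupted
#' by quiescent episodes at standard metabolic rate (SMR) and brief activity
#' bursts. The analytic excess post-exercise oxygen consumption above the
#' routine baseline is \eqn{(MMR - RMR)\,\tau}, stored as `epoc_true`.
#'
#' @param smr_true Standard metabolic rate, mg O2 h^-1 kg^-1.
#' @param rmr_true Routine metabolic rate, mg O2 h^-1 kg^-1.
#' @param mmr_true Maximum metabolic rate, mg O2 h^-1 kg^-1.
#' @param tau_recovery Exponential recovery time constant, hours.
#' @param q10_smr Q10 thermal coefficient applied to SMR when a cohort is
#'   expanded across experimental temperatures.
#' @param background_fraction Microbial (background) respiration as a
#'   fraction of whole-animal SMR.
#' @param noise_sd Gaussian sensor noise on oxygen concentration, mg O2 L^-1.
#' @param activity_burst_rate Rate of spontaneous activity bursts, events per
#'   hour.
#' @param quiescent_fraction Long-run fraction of post-recovery time spent in
#'   the quiescent (SMR) state.
#' @param quiescence_onset Hours after exercise before quiescent episodes can
#'   begin; defaults to `4 * tau_recovery`, by which time the recovery excess
#'   has decayed to under 2% of its initial value.
#' @param seed Integer seed driving every stochastic element of this animal's
#'   simulated data.
#'
#' @return A one-row tibble of class `simulation_truth`.
#' @examples
#' simulation_truth(rmr_true = 50, mmr_true = 110, tau_recovery = 3)$epoc_true
#' @export
simulation_truth <- function(smr_true = 30,
                             rmr_true = 36,
                             mmr_true = 110,
                             tau_recovery = 3,
                             q10_smr = 3.3,
                             background_fraction = 0.05,
                             noise_sd = 0.01,
                             activity_burst_rate = 0.2,
                             quiescent_fraction = 0.2,
                             quiescence_onset = NULL,
                             seed = 1L) {
  if (!is.finite(tau_recovery) || tau_recovery <= 0) {
    abort("`tau_recovery` must be a positive number.")
  }
  if (!(smr_true <= rmr_true && rmr_true < mmr_true)) {
    abort("Need smr_true <= rmr_true < mmr_true.")
  }
  if (q10_smr <= 0) abort("`q10_smr` must be positive.")
  if (background_fraction < 0) abort("`background_fraction` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (quiescent_fraction < 0 || quiescent_fraction >= 1) {
    abort("`quiescent_fraction` must be in [0, 1).")
  }
  out <- tibble(
    smr_true = smr_true, rmr_true = rmr_true, mmr_true = mmr_true,
    tau_recovery = tau_recovery,
    epoc_true = (mmr_true - rmr_true) * tau_recovery,
    q10_smr = q10_smr,
    background_fraction = background_fraction,
    noise_sd = noise_sd,
    activity_burst_rate = activity_burst_rate,
    quiescent_fraction = quiescent_fraction,
    quiescence_onset = quiescence_onset %||% (4 * tau_recovery),
    seed = as.integer(seed)
  )
  class(out) <- c("simulation_truth", class(out))
  out
}

#' Respirometry chamber and trial geometry
#'
#' Defaults follow a typical large-decapod setup: a 10 L chamber, a ~1 kg
#' animal displacing ~1 L, six-minute sealed measure phases alternating with
#' eight-minute flushes, oxygen sampled every 10 s, and 48 h trials.
#'
#' @param chamber_volume Chamber water volume, L.
#' @param body_volume Animal body volume, L; if `NULL`, derived as
#'   `body_mass / body_density` (kg over g mL^-1 gives L).
#' @param body_mass Animal body mass, kg.
#' @param body_density Default body density, g mL^-1.
#' @param measure_duration Sealed measure phase length, s.
#' @param flush_duration Flush phase length, s.
#' @param sample_interval Oxygen sampling interval, s; must divide the
#'   measure duration.
#' @param saturation_concentration Fully air-saturated oxygen concentration
#'   at the trial temperature, mg O2 L^-1 (supplied, not computed).
#' @param trial_duration Trial length, hours.
#'
#' @return A list of class `chamber_spec`, including the effective volume
#'   `effective_volume = chamber_volume - body_volume`.
#' @export
chamber_spec <- function(chamber_volume = 10,
                         body_volume = NULL,
                         body_mass = 1.12,
                         body_density = 1.12,
                         measure_duration = 360,
                         flush_duration = 480,
                         sample_interval = 10,
                         saturation_concentration = 8,
                         trial_duration = 48) {
  if (body_mass <= 0) abort("`body_mass` must be positive.")
  body_volume <- body_volume %||% (body_mass / body_density)
  v_eff <- chamber_volume - body_volume
  if (v_eff <= 0) {
    abort("Effective volume (chamber_volume - body_volume) must be positive.")
  }
  if (sample_interval <= 0 || measure_duration %% sample_interval != 0) {
    abort("`sample_interval` must be positive and divide `measure_duration`.")
  }
  if (flush_duration <= 0) abort("`flush_duration` must be positive.")
  if (saturation_concentration <= 0) {
    abort("`saturation_concentration` must be positive.")
  }
  structure(
    list(
      chamber_volume = chamber_volume, body_volume = body_volume,
      body_mass = body_mass, body_density = body_density,
      effective_volume = v_eff,
      measure_duration = measure_duration, flush_duration = flush_duration,
      sample_interval = sample_interval,
      saturation_concentration = saturation_concentration,
      trial_duration = trial_duration
    ),
    class = "chamber_spec"
  )
}

#' Factorial cohort design
#'
#' Describes a fully factorial thermal-acclimation by acute-temperature
#' design: every animal (species x acclimation group x replicate) is measured
#' at every experimental temperature. The default grid is the
#' 14.0 / 17.5 / 21.5 degC annual-average, current-summer and projected
#' future-summer habitat temperatures used for both factors.
#'
#' @param species Character vector of species labels.
#' @param acclimation_temps Chronic holding temperatures, degC.
#' @param experimental_temps Acute trial temperatures, degC.
#' @param n_per_cell Animals per species x acclimation cell.
#' @param acclimation_effect_smr Multiplicative change of SMR per step up the
#'   acclimation-temperature ladder (< 1 encodes the "plastic floor" of
#'   warm-acclimated animals; 0.81 per step compounds to a ~34% reduction
#'   over two steps).
#' @param acclimation_effect_tau Multiplicative change of the recovery time
#'   constant per acclimation step (< 1: warm-acclimated animals recover
#'   faster).
#' @param q10_map Named list of Q10 coefficients per trait used to scale
#'   rates across experimental temperature; `smr` and `mmr` are used.
#' @param t_ref Reference experimental temperature, degC, at which the base
#'   truth applies; defaults to the middle (current-summer) temperature,
#'   where the base-truth magnitudes sit.
#' @param between_animal_cv Lognormal coefficient of variation of individual
#'   trait multipliers.
#' @param flips_base Expected tail-flip count for an animal with the base
#'   EPOC; realised counts scale with each record's true EPOC, giving a known
#'   positive escape--EPOC coupling.
#' @param speed_mean,speed_sd Mean and SD of true escape speed, cm s^-1.
#'
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(species = c("J. edwardsii", "S. verreauxi"),
                          acclimation_temps = c(14, 17.5, 21.5),
                          experimental_temps = c(14, 17.5, 21.5),
                          n_per_cell = 6,
                          acclimation_effect_smr = 0.81,
                          acclimation_effect_tau = 0.78,
                          q10_map = list(smr = 3.3, mmr = 1.4),
                          t_ref = 17.5,
                          between_animal_cv = 0.08,
                          flips_base = 20,
                          speed_mean = 60,
                          speed_sd = 6) {
  if (length(species) < 1 || length(acclimation_temps) < 1 ||
      length(experimental_temps) < 1 || n_per_cell < 1) {
    abort("Cohort design must be non-empty.")
  }
  structure(
    list(
      species = species,
      acclimation_temps = sort(acclimation_temps),
      experimental_temps = sort(experimental_temps),
      n_per_cell = as.integer(n_per_cell),
      acclimation_effect_smr = acclimation_effect_smr,
      acclimation_effect_tau = acclimation_effect_tau,
      q10_map = q10_map, t_ref = t_ref,
      between_animal_cv = between_animal_cv,
      flips_base = flips_base,
      speed_mean = speed_mean, speed_sd = speed_sd
    ),
    class = "cohort_design"
  )
}

# Run code under a temporary RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Simulate the true post-exercise oxygen-consumption trajectory
#'
#' Evaluates the recovery model on a regular time grid: exponential decay
#' from MMR towards the routine baseline, with (optionally) quiescent
#' episodes dipping to SMR after `quiescence_onset` and sparse activity
#' bursts. MO2 is capped at `mmr_true` (the aerobic ceiling).
#'
#' @param truth A [simulation_truth()] row.
#' @param duration Trajectory length, hours; at least `5 * tau_recovery` is
#'   recommended so the excess has decayed away.
#' @param step Time step, hours.
#' @param quiescence,bursts Logical switches for the two stochastic
#'   components; with both `FALSE` the trajectory is the closed-form curve.
#'
#' @return A tibble with `time_h`, `mo2` (mg O2 h^-1 kg^-1) and `state`
#'   (`"routine"`, `"quiescent"` or `"burst"`).
#' @export
simulate_mo2_trajectory <- function(truth, duration, step = 0.02,
                                    quiescence = TRUE, bursts = TRUE) {
  if (!is.finite(step) || step <= 0) abort("`step` must be positive.")
  if (!is.finite(duration) || duration <= 0) abort("`duration` must be positive.")
  if (truth$tau_recovery <= 0) abort("`tau_recovery` must be positive.")

  time_h <- seq(0, duration, by = step)
  excess <- (truth$mmr_true - truth$rmr_true) * exp(-time_h / truth$tau_recovery)
  baseline <- rep(truth$rmr_true, length(time_h))
  state <- rep("routine", length(time_h))

  with_seed(derive_seed(truth$seed, "trajectory"), {
    f <- truth$quiescent_fraction
    if (quiescence && f > 0) {
      # Alternating exponential routine/quiescent episodes after onset; mean
      # episode lengths chosen so the long-run quiescent fraction equals f.
      q_mean <- 0.5
      r_mean <- q_mean * (1 - f) / f
      t_cur <- truth$quiescence_onset
      while (t_cur < duration) {
        t_cur <- t_cur + stats::rexp(1, rate = 1 / r_mean)
        q_len <- stats::rexp(1, rate = 1 / q_mean)
        idx <- time_h >= t_cur & time_h < t_cur + q_len
        baseline[idx] <- truth$smr_true
        state[idx] <- "quiescent"
        t_cur <- t_cur + q_len
      }
    }
    if (bursts && truth$activity_burst_rate > 0) {
      n_burst <- rpois(1, truth$activity_burst_rate * duration)
      if (n_burst > 0) {
        starts <- runif(n_burst, 0, duration)
        amps <- runif(n_burst, 0.05, 0.15) * (truth$mmr_true - truth$smr_true)
        for (k in seq_len(n_burst)) {
          idx <- time_h >= starts[k] & time_h < starts[k] + 0.1
          baseline[idx] <- baseline[idx] + amps[k]
          state[idx] <- "burst"
        }
      }
    }
  })

  tibble(
    time_h = time_h,
    mo2 = pmin(baseline + excess, truth$mmr_true),
    state = state
  )
}

#' Forward-simulate the chamber oxygen trace for one trial
#'
#' Converts a true MO2 trajectory into the oxygen-concentration series an
#' intermittent-flow respirometer would record. During sealed measure phases
#' the concentration falls at `(MO2(t) * mass + background) / V_eff`; during
#' flushes it relaxes exponentially back towards saturation, reaching > 99%
#' of it by the end of the flush. Gaussian sensor noise is added per sample
#' and readings are capped at the saturation concentration.
#'
#' @param trajectory Output of [simulate_mo2_trajectory()]; must cover the
#'   trial duration.
#' @param chamber A [chamber_spec()].
#' @param truth The [simulation_truth()] that generated the trajectory
#'   (provides background fraction, noise and the seed).
#' @param temperature Trial temperature recorded alongside the trace, degC.
#' @param channel_id Chamber/channel label.
#'
#' @return A tibble with `time_s`, `o2` (mg O2 L^-1), `temperature`,
#'   `channel_id`, `phase` (`"measure"`/`"flush"`) and `cycle` (measure-cycle
#'   index, `NA` during flushes).
#' @export
synthesize_trace <- function(trajectory, chamber, truth,
                             temperature = NA_real_,
                             channel_id = "ch1") {
  stopifnot(inherits(chamber, "chamber_spec"))
  trial_s <- chamber$trial_duration * 3600
  if (max(trajectory$time_h) * 3600 < trial_s - 1e-6) {
    abort("Trajectory does not cover the trial duration.")
  }
  dt <- chamber$sample_interval
  period <- chamber$measure_duration + chamber$flush_duration
  n_cycles <- floor(trial_s / period)
  if (n_cycles < 1) abort("Trial shorter than one measure/flush cycle.")
  sat <- chamber$saturation_concentration
  v_eff <- chamber$effective_volume
  mass <- chamber$body_mass
  bg_rate <- truth$background_fraction * truth$smr_true * mass # mg O2 h^-1
  k_flush <- 5 / chamber$flush_duration # e^-5: > 99% recovered per flush

  mo2_at <- function(t_s) {
    approx(trajectory$time_h, trajectory$mo2, xout = t_s / 3600, rule = 2)$y
  }

  meas_off <- seq(0, chamber$measure_duration - dt, by = dt)
  flush_off <- seq(chamber$measure_duration, period - dt, by = dt)
  pieces <- vector("list", n_cycles)
  conc0 <- sat
  for (cyc in seq_len(n_cycles)) {
    t0 <- (cyc - 1) * period
    tm <- t0 + meas_off
    rate <- (mo2_at(tm) * mass + bg_rate) / 3600 / v_eff # mg L^-1 s^-1
    conc_m <- conc0 - cumsum(c(0, rate[-length(rate)] * dt))
    if (any(conc_m <= 0)) {
      abort(paste0(
        "Simulated oxygen concentration became non-positive in cycle ", cyc,
        "; parameters imply an implausibly fast drawdown."
      ))
    }
    conc_end <- conc_m[length(conc_m)] -
      rate[length(rate)] * dt # at flush start
    tf <- t0 + flush_off
    elapsed <- tf - (t0 + chamber$measure_duration)
    conc_f <- sat - (sat - conc_end) * exp(-k_flush * elapsed)
    pieces[[cyc]] <- tibble(
      time_s = c(tm, tf),
      o2 = c(conc_m, conc_f),
      phase = rep(c("measure", "flush"), c(length(tm), length(tf))),
      cycle = c(rep(cyc, length(tm)), rep(NA_integer_, length(tf)))
    )
    conc0 <- sat - (sat - conc_end) * exp(-k_flush * chamber$flush_duration)
  }
  out <- bind_rows(pieces)
  if (truth$noise_sd > 0) {
    noise <- with_seed(
      derive_seed(truth$seed, "trace"),
      rnorm(nrow(out), 0, truth$noise_sd)
    )
    out$o2 <- pmin(out$o2 + noise, sat)
  }
  out$temperature <- temperature
  out$channel_id <- channel_id
  out[, c("time_s", "o2", "temperature", "channel_id", "phase", "cycle")]
}

#' Simulate a chase-video click track with known escape speed
#'
#' Produces the click table a video-annotation session yields: one row per
#' mouse click, two consecutive clicks (before/after) delimiting each tail
#' flip. Every event's displacement/frame-gap ratio corresponds exactly to
#' `true_speed` after calibration; directions are random.
#'
#' @param true_speed True escape speed, cm s^-1.
#' @param n_flips Number of tail-flip events; 0 gives an empty (valid) track.
#' @param fps Video frame rate, frames s^-1.
#' @param px_per_cm Pixel-to-centimetre calibration, px cm^-1.
#' @param seed Integer seed.
#' @param start Starting pixel position, length-2 numeric.
#'
#' @return A tibble of clicks (`frame`, `x`, `y`) with attributes `fps` and
#'   `px_per_cm`.
#' @export
simulate_chase_track <- function(true_speed, n_flips, fps = 24,
                                 px_per_cm = 10, seed = 1L,
                                 start = c(500, 500)) {
  if (fps <= 0 || px_per_cm <= 0) abort("`fps` and `px_per_cm` must be positive.")
  if (true_speed < 0 || n_flips < 0) {
    abort("`true_speed` and `n_flips` must be non-negative.")
  }
  if (n_flips == 0) {
    out <- tibble(frame = integer(), x = numeric(), y = numeric())
  } else {
    out <- with_seed(seed, {
      gaps <- sample(6:30, n_flips, replace = TRUE)
      rests <- sample(12:72, n_flips, replace = TRUE)
      theta <- runif(n_flips, 0, 2 * pi)
      d_px <- true_speed * gaps / fps * px_per_cm
      frame <- integer(2 * n_flips)
      x <- y <- numeric(2 * n_flips)
      f_cur <- 1L
      pos <- start
      for (k in seq_len(n_flips)) {
        i <- 2 * k - 1
        frame[i] <- f_cur
        x[i] <- pos[1]; y[i] <- pos[2]
        pos <- pos + d_px[k] * c(cos(theta[k]), sin(theta[k]))
        f_cur <- f_cur + gaps[k]
        frame[i + 1] <- f_cur
        x[i + 1] <- pos[1]; y[i + 1] <- pos[2]
        f_cur <- f_cur + rests[k]
      }
      tibble(frame = frame, x = x, y = y)
    })
  }
  attr(out, "fps") <- fps
  attr(out, "px_per_cm") <- px_per_cm
  out
}

#' Simulate a factorial acclimation-by-temperature cohort
#'
#' Expands a base truth across the full species x acclimation x experimental
#' temperature grid. SMR (and the routine baseline with it) scales across
#' experimental temperature as \eqn{SMR \cdot Q_{10}^{(T - T_{ref})/10}} and
#' multiplicatively per acclimation step; MMR scales with its own (lower)
#' Q10 and no acclimation effect; the recovery time constant shrinks with
#' warm acclimation. Each trial record carries its own [simulation_truth()]
#' so estimates can be compared to truth record by record.
#'
#' @param design A [cohort_design()].
#' @param base_truth A [simulation_truth()] describing the reference animal
#'   at `design$t_ref` and the coldest acclimation group.
#' @param chamber A [chamber_spec()] shared by all trials.
#' @param include_traces,include_tracks Generate the raw oxygen traces /
#'   chase tracks (set `FALSE` to obtain only records and truths, e.g. for
#'   trait-level analyses).
#'
#' @return A list with `animals` (one row per animal x experimental
#'   temperature, animal metadata plus the record's true parameters),
#'   `traces` and `tracks` (long tibbles keyed by `trial_id`, or `NULL`).
#' @export
simulate_cohort <- function(design, base_truth = simulation_truth(),
                            chamber = chamber_spec(),
                            include_traces = TRUE, include_tracks = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  acc_levels <- design$acclimation_temps
  grid <- tidyr::expand_grid(
    species = design$species,
    acclimation_temp = acc_levels,
    replicate = seq_len(design$n_per_cell)
  ) %>%
    mutate(animal_id = sprintf(
      "%s_acc%04.1f_r%02d",
      gsub("[^A-Za-z]", "", .data$species), .data$acclimation_temp,
      .data$replicate
    ))

  # Per-animal lognormal trait multipliers from the animal's substream.
  cv <- design$between_animal_cv
  sdlog <- sqrt(log(1 + cv^2))
  animal_fx <- purrr::pmap_dfr(grid, function(species, acclimation_temp,
                                              replicate, animal_id) {
    with_seed(derive_seed(base_truth$seed, animal_id), {
      m <- exp(rnorm(3, -sdlog^2 / 2, sdlog))
      tibble(
        animal_id = animal_id,
        mult_smr = m[1], mult_mmr = m[2], mult_tau = m[3],
        body_mass = max(0.4, rnorm(1, 1.07, 0.1)),
        carapace_length = max(6, rnorm(1, 12, 1)),
        sex = sample(c("m", "f"), 1),
        true_speed = max(10, rnorm(1, design$speed_mean, design$speed_sd))
      )
    })
  })

  records <- grid %>%
    left_join(animal_fx, by = "animal_id") %>%
    tidyr::expand_grid(experimental_temp = design$experimental_temps) %>%
    mutate(
      body_volume = .data$body_mass / chamber$body_density,
      acc_step = match(.data$acclimation_temp, acc_levels) - 1L,
      trial_id = sprintf("%s_T%04.1f", .data$animal_id, .data$experimental_temp)
    )

  q10_smr <- design$q10_map$smr %||% base_truth$q10_smr
  q10_mmr <- design$q10_map$mmr %||% 1.4
  t_ref <- design$t_ref
  rmr_ratio <- base_truth$rmr_true / base_truth$smr_true

  records <- records %>%
    mutate(
      smr_true = base_truth$smr_true * .data$mult_smr *
        q10_smr^((.data$experimental_temp - t_ref) / 10) *
        design$acclimation_effect_smr^.data$acc_step,
      rmr_true = .data$smr_true * rmr_ratio,
      mmr_true = base_truth$mmr_true * .data$mult_mmr *
        q10_mmr^((.data$experimental_temp - t_ref) / 10),
      tau_recovery = base_truth$tau_recovery * .data$mult_tau *
        design$acclimation_effect_tau^.data$acc_step,
      epoc_true = (.data$mmr_true - .data$rmr_true) * .data$tau_recovery,
      seed = purrr::map_int(.data$trial_id, ~ derive_seed(base_truth$seed, .x))
    )
  bad <- records$rmr_true >= records$mmr_true
  if (any(bad)) {
    abort("Cohort scaling produced rmr_true >= mmr_true; check Q10/acclimation settings.")
  }

  traces <- NULL
  tracks <- NULL
  if (include_traces) {
    traces <- purrr::map(seq_len(nrow(records)), function(i) {
      rec <- records[i, ]
      truth_i <- simulation_truth(
        smr_true = rec$smr_true, rmr_true = rec$rmr_true,
        mmr_true = rec$mmr_true, tau_recovery = rec$tau_recovery,
        q10_smr = q10_smr,
        background_fraction = base_truth$background_fraction,
        noise_sd = base_truth$noise_sd,
        activity_burst_rate = base_truth$activity_burst_rate,
        quiescent_fraction = base_truth$quiescent_fraction,
        seed = rec$seed
      )
      cham_i <- chamber
      cham_i$body_mass <- rec$body_mass
      cham_i$body_volume <- rec$body_volume
      cham_i$effective_volume <- cham_i$chamber_volume - rec$body_volume
      traj <- simulate_mo2_trajectory(truth_i, duration = chamber$trial_duration)
      synthesize_trace(traj, cham_i, truth_i,
        temperature = rec$experimental_temp, channel_id = rec$trial_id
      ) %>%
        mutate(trial_id = rec$trial_id, animal_id = rec$animal_id)
    }) %>% bind_rows()
  }
  if (include_tracks) {
    epoc_ref <- base_truth$epoc_true
    tracks <- purrr::map(seq_len(nrow(records)), function(i) {
      rec <- records[i, ]
      n_flips <- with_seed(
        derive_seed(rec$seed, "flips"),
        rpois(1, design$flips_base * rec$epoc_true / epoc_ref)
      )
      simulate_chase_track(
        true_speed = rec$true_speed, n_flips = n_flips,
        seed = derive_seed(rec$seed, "track")
      ) %>%
        mutate(trial_id = rec$trial_id, animal_id = rec$animal_id)
    }) %>% bind_rows()
  }

  records <- records %>%
    select(-"mult_smr", -"mult_mmr", -"mult_tau", -"acc_step")
  list(animals = records, traces = traces, tracks = tracks)
}
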