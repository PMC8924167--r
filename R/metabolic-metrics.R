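# Trait derivation from one per-cycle MO2 series: standard, routine and
# maximum metabolic rate, aerobic and factorial scope, recovery time, EPOC
# and recovery rate.

accepted_series <- function(series) {
  s <- series %>% filter(.data$accepted) %>% arrange(.data$cycle_time_h)
  if (nrow(s) == 0) abort("No accepted cycles in MO2 series.")
  s
}

#' Standard metabolic rate: mean of the lowest decile of MO2 values
#'
#' SMR is estimated as the mean of the lowest `ceiling(q * n)` accepted MO2
#' values over the whole trial (default q = 10%), ties broken by cycle
#' order.
#'
#' @param series An `mo2_series` (or any tibble with `mo2`, `accepted`,
#'   `cycle_time_h` columns).
#' @param quantile Fraction of lowest values averaged.
#' @return SMR, mg O2 h^-1 kg^-1.
#' @export
compute_smr <- function(series, quantile = 0.1) {
  s <- accepted_series(series)
  n <- nrow(s)
  if (n < 10) {
    abort(paste0(
      "SMR needs at least 10 accepted cycles for a robust lowest-decile mean; got ",
      n, "."
    ))
  }
  k <- ceiling(quantile * n)
  mean(sort(s$mo2, method = "radix")[seq_len(k)])
}

#' Maximum metabolic rate: the single highest accepted MO2
#'
#' @inheritParams compute_smr
#' @return MMR, mg O2 h^-1 kg^-1.
#' @export
compute_mmr <- function(series) {
  s <- accepted_series(series)
  max(s$mo2)
}

#' Routine metabolic rate over the post-recovery window
#'
#' Mean and standard deviation of accepted MO2 from `window_start` hours
#' after the trial start until the trial end.
#'
#' @inheritParams compute_smr
#' @param window_start Start of the routine window, h (default 16, the time
#'   by which all animals are expected to have recovered).
#' @return A list with `rmr` and `rmr_sd` (mg O2 h^-1 kg^-1).
#' @export
compute_rmr <- function(series, window_start = 16) {
  s <- accepted_series(series)
  w <- s %>% filter(.data$cycle_time_h >= window_start)
  if (nrow(w) == 0) {
    abort(paste0("No accepted cycles after ", window_start, " h; trial too short."))
  }
  list(rmr = mean(w$mo2), rmr_sd = if (nrow(w) > 1) sd(w$mo2) else 0)
}

#' Recovery time: third drop below the routine threshold
#'
#' The recovery threshold is RMR + 1 SD (the SD of the routine window). The
#' trial is marked recovered at the cycle time of the third accepted cycle
#' whose MO2 falls below the threshold -- counted cumulatively from the
#' trial start by default, or as the third cycle of the first run of three
#' consecutive sub-threshold cycles with `rule = "consecutive"`.
#'
#' @inheritParams compute_smr
#' @param rmr,rmr_sd Routine metabolic rate and its SD (see [compute_rmr()]).
#' @param rule `"cumulative"` (default) or `"consecutive"` counting of
#'   sub-threshold cycles.
#' @return Recovery time in hours, or `NA` (with a warning) if fewer than
#'   three cycles fall below the threshold ("not recovered").
#' @export
compute_recovery_time <- function(series, rmr, rmr_sd,
                                  rule = c("cumulative", "consecutive")) {
  rule <- match.arg(rule)
  s <- accepted_series(series)
  threshold <- rmr + rmr_sd
  below <- s$mo2 < threshold
  idx <- NA_integer_
  if (rule == "cumulative") {
    hits <- which(below)
    if (length(hits) >= 3) idx <- hits[3]
  } else {
    runs <- rle(below)
    run_end <- cumsum(runs$lengths)
    cand <- which(runs$values & runs$lengths >= 3)
    if (length(cand) > 0) {
      idx <- run_end[cand[1]] - runs$lengths[cand[1]] + 3L
    }
  }
  if (is.na(idx)) {
    warn("Fewer than three cycles below RMR + 1 SD; trial not recovered.")
    return(NA_real_)
  }
  s$cycle_time_h[idx]
}

#' Excess post-exercise oxygen consumption (EPOC)
#'
#' Trapezoidal integral of accepted MO2 above a baseline, from the first
#' measured cycle until recovery time. The default baseline is RMR; SMR or
#' no baseline (the literal area under the curve) are available. Negative
#' excess (MO2 below baseline) contributes zero, never negative area.
#'
#' @inheritParams compute_smr
#' @param recovery_time Upper integration limit, h.
#' @param baseline_mode `"rmr"`, `"smr"` or `"none"`.
#' @param rmr,smr Baseline values, required for the matching mode.
#' @return EPOC, mg O2 kg^-1.
#' @export
compute_epoc <- function(series, recovery_time,
                         baseline_mode = c("rmr", "smr", "none"),
                         rmr = NULL, smr = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  if (is.null(recovery_time) || is.na(recovery_time)) {
    abort("EPOC is undefined without a recovery time.")
  }
  s <- accepted_series(series) %>%
    filter(.data$cycle_time_h <= recovery_time)
  if (nrow(s) < 2) abort("Too few cycles before recovery time to integrate.")
  baseline <- switch(baseline_mode,
    rmr = rmr %||% abort("Supply `rmr` for baseline_mode = 'rmr'."),
    smr = smr %||% abort("Supply `smr` for baseline_mode = 'smr'."),
    none = 0
  )
  y <- pmax(s$mo2 - baseline, 0)
  t <- s$cycle_time_h
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Recovery rate: EPOC repaid per hour
#'
#' @param epoc EPOC, mg O2 kg^-1.
#' @param recovery_time Recovery time, h.
#' @return Recovery rate, mg O2 h^-1 kg^-1.
#' @export
compute_recovery_rate <- function(epoc, recovery_time) {
  if (is.null(recovery_time) || is.na(recovery_time) || recovery_time <= 0) {
    abort("Recovery rate needs a positive, defined recovery time.")
  }
  epoc / recovery_time
}

#' Full metabolic trait summary for one trial
#'
#' Derives the complete trait set from one per-cycle MO2 series: SMR, RMR
#' (+ SD), MMR, aerobic scope (MMR - SMR), factorial scope (MMR / SMR),
#' recovery time, EPOC and recovery rate. All estimator settings are echoed
#' as columns for provenance. An SMR/RMR/MMR ordering violation is reported
#' in `qc_ordering_ok`, never silently reordered.
#'
#' @inheritParams compute_smr
#' @param rmr_window_start Start of the routine window, h.
#' @param baseline_mode EPOC baseline: `"rmr"` (default), `"smr"`, `"none"`.
#' @param recovery_rule Sub-threshold counting rule, `"cumulative"` or
#'   `"consecutive"`.
#' @param smr_quantile Lowest fraction of MO2 values averaged for SMR.
#' @return A one-row tibble of class `metabolic_summary`.
#' @export
metabolic_summary <- function(series, rmr_window_start = 16,
                              baseline_mode = "rmr",
                              recovery_rule = "cumulative",
                              smr_quantile = 0.1) {
  smr <- compute_smr(series, quantile = smr_quantile)
  mmr <- compute_mmr(series)
  rmr_fit <- compute_rmr(series, window_start = rmr_window_start)
  recovery_time <- withCallingHandlers(
    compute_recovery_time(series, rmr_fit$rmr, rmr_fit$rmr_sd,
      rule = recovery_rule
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  recovered <- !is.na(recovery_time)
  epoc <- if (recovered) {
    compute_epoc(series, recovery_time,
      baseline_mode = baseline_mode,
      rmr = rmr_fit$rmr, smr = smr
    )
  } else {
    NA_real_
  }
  recovery_rate <- if (recovered && recovery_time > 0) {
    epoc / recovery_time
  } else {
    NA_real_
  }
  out <- tibble(
    smr = smr, rmr = rmr_fit$rmr, rmr_sd = rmr_fit$rmr_sd, mmr = mmr,
    aerobic_scope = mmr - smr,
    factorial_scope = mmr / smr,
    recovery_time = recovery_time,
    epoc = epoc,
    recovery_rate = recovery_rate,
    recovered = recovered,
    qc_ordering_ok = smr <= rmr_fit$rmr & rmr_fit$rmr <= mmr,
    n_cycles = nrow(series),
    n_accepted = sum(series$accepted),
    baseline_mode = baseline_mode,
    recovery_rule = recovery_rule,
    rmr_window_start = rmr_window_start,
    smr_quantile = smr_quantile
  )
  class(out) <- c("metabolic_summary", class(out))
  out
}

#' @describeIn metabolic_summary `tidy()` method for an `mo2_series`: the
#'   per-cycle table with QC flags.
#' @param x An `mo2_series`.
#' @param ... Unused.
#' @export
tidy.mo2_series <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @describeIn metabolic_summary `glance()` method for an `mo2_series`: the
#'   one-row [metabolic_summary()].
#' @export
glance.mo2_series <- function(x, ...) {
  metabolic_summary(x, ...)
}
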