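# Per-cycle oxygen-uptake extraction: OLS slope of the sealed-phase oxygen
# decline, scaled by the chamber's effective volume, corrected for microbial
# background respiration and normalised to body mass.

#' Fit the oxygen-decline slope of one measure cycle
#'
#' Ordinary least-squares regression of oxygen concentration on time within
#' a sealed measure phase. The slope is reported in mg O2 L^-1 h^-1 and is
#' expected to be negative for a respiring animal.
#'
#' @param time_s Sample times within the cycle, s.
#' @param o2 Oxygen concentrations, mg O2 L^-1.
#' @return A list with `slope` (mg O2 L^-1 h^-1), `r2` (`NA` when the
#'   concentration is constant) and `n`.
#' @examples
#' fit_cycle_slope(c(0, 180, 360), c(8.0, 7.75, 7.5))
#' @export
fit_cycle_slope <- function(time_s, o2) {
  n <- length(time_s)
  if (n < 3) abort("A measure cycle needs at least 3 samples to fit a slope.")
  t_h <- time_s / 3600
  tc <- t_h - mean(t_h)
  yc <- o2 - mean(o2)
  sxx <- sum(tc^2)
  slope <- sum(tc * yc) / sxx
  sst <- sum(yc^2)
  r2 <- if (sst <= .Machine$double.eps * n) NA_real_ else {
    1 - sum((yc - slope * tc)^2) / sst
  }
  list(slope = slope, r2 = r2, n = n)
}

#' Convert a concentration slope into a mass-specific oxygen uptake rate
#'
#' \deqn{MO_2 = \frac{-\text{slope} \times V_{eff} - \text{background}}{\text{mass}}}
#' with \eqn{V_{eff}} the chamber volume minus the animal's body volume.
#'
#' @param slope Concentration slope, mg O2 L^-1 h^-1 (negative for uptake).
#' @param chamber A [chamber_spec()] (provides `effective_volume` and the
#'   default body mass).
#' @param body_mass Animal mass, kg; defaults to the chamber's.
#' @param background_rate Background (microbial) respiration, mg O2 h^-1.
#' @return Mass-specific MO2, mg O2 h^-1 kg^-1.
#' @examples
#' ch <- chamber_spec(chamber_volume = 10, body_volume = 1, body_mass = 1)
#' mo2_from_slope(-5, ch) # 45
#' @export
mo2_from_slope <- function(slope, chamber, body_mass = NULL,
                           background_rate = 0) {
  stopifnot(inherits(chamber, "chamber_spec"))
  body_mass <- body_mass %||% chamber$body_mass
  if (chamber$effective_volume <= 0) {
    abort("Effective volume must be positive (animal larger than chamber?).")
  }
  if (body_mass <= 0) abort("`body_mass` must be positive.")
  (-slope * chamber$effective_volume - background_rate) / body_mass
}

#' Background respiration as a function of trial time
#'
#' Blank-chamber respiration is measured before and after a trial; in
#' between it is linearly interpolated. If the post-trial rate is missing
#' the pre-trial rate is used throughout, with a warning.
#'
#' @param background A list or one-row data frame with `pre_rate` and
#'   `post_rate` (mg O2 h^-1), or a single constant rate.
#' @param trial_duration_h Trial length, h.
#' @return A function of time (h) returning the background rate (mg O2 h^-1).
#' @export
background_correction <- function(background, trial_duration_h) {
  if (is.numeric(background) && length(background) == 1) {
    background <- list(pre_rate = background, post_rate = background)
  }
  pre <- background$pre_rate
  post <- background$post_rate
  if (is.null(pre) || is.na(pre)) abort("Background `pre_rate` is required.")
  if (pre < 0 || (!is.null(post) && !is.na(post) && post < 0)) {
    abort("Background rates must be non-negative.")
  }
  if (is.null(post) || is.na(post)) {
    warn("Background post_rate missing; using constant pre_rate.")
    post <- pre
  }
  force(trial_duration_h)
  function(t_h) {
    pre + (post - pre) * pmin(pmax(t_h / trial_duration_h, 0), 1)
  }
}

#' Flag cycles whose oxygen saturation fell below a floor
#'
#' @param trace An oxygen-trace tibble (with `phase` and `cycle`).
#' @param saturation_concentration Air-saturated concentration, mg O2 L^-1.
#' @param floor_percent Minimum acceptable saturation, percent.
#' @return A tibble per measure cycle with `min_saturation_pct` and
#'   `saturation_flag`.
#' @export
qc_saturation <- function(trace, saturation_concentration,
                          floor_percent = 77) {
  if (saturation_concentration <= 0) {
    abort("`saturation_concentration` must be positive.")
  }
  trace %>%
    filter(.data$phase == "measure") %>%
    group_by(cycle = .data$cycle) %>%
    summarise(
      min_saturation_pct = min(.data$o2) / saturation_concentration * 100,
      .groups = "drop"
    ) %>%
    mutate(saturation_flag = .data$min_saturation_pct < floor_percent)
}

#' Extract the per-cycle MO2 series from an oxygen trace
#'
#' Fits an OLS slope per measure cycle, converts it to mass-specific MO2
#' with the effective-volume scaling and background correction, and attaches
#' quality-control flags. Cycles are flagged (never silently dropped or
#' clipped) for: fewer than 3 samples, regression r-squared below
#' `r2_threshold`, minimum saturation below `saturation_floor` percent, and
#' negative corrected MO2. Flag-free cycles are marked `accepted`.
#'
#' @param trace Oxygen-trace tibble with `phase` and `cycle` columns.
#' @param chamber A [chamber_spec()].
#' @param body_mass Animal mass, kg; defaults to the chamber's.
#' @param background Passed to [background_correction()]; a constant rate,
#'   a `pre_rate`/`post_rate` record, or `NULL` for no correction.
#' @param r2_threshold Minimum acceptable regression r-squared.
#' @param saturation_floor Minimum acceptable saturation, percent.
#' @return A tibble of class `mo2_series`: one row per measure cycle with
#'   `cycle`, `cycle_time_h` (phase midpoint), `slope`, `r2`, `mo2`,
#'   `background_rate`, the QC flag columns and `accepted`.
#' @export
extract_mo2 <- function(trace, chamber, body_mass = NULL, background = NULL,
                        r2_threshold = 0.9, saturation_floor = 77) {
  stopifnot(inherits(chamber, "chamber_spec"))
  body_mass <- body_mass %||% chamber$body_mass
  meas <- trace %>% filter(.data$phase == "measure", !is.na(.data$cycle))
  if (nrow(meas) == 0) abort("Trace contains no measure-phase samples.")

  bg_fun <- if (is.null(background)) {
    function(t_h) rep(0, length(t_h))
  } else {
    background_correction(background, max(trace$time_s) / 3600)
  }

  fits <- meas %>%
    group_by(cycle = .data$cycle) %>%
    summarise(
      cycle_time_h = mean(range(.data$time_s)) / 3600,
      n_samples = n(),
      slope = if (n() >= 3) fit_cycle_slope(.data$time_s, .data$o2)$slope else NA_real_,
      r2 = if (n() >= 3) fit_cycle_slope(.data$time_s, .data$o2)$r2 else NA_real_,
      min_o2 = min(.data$o2),
      .groups = "drop"
    ) %>%
    arrange(.data$cycle_time_h)

  fits <- fits %>%
    mutate(
      background_rate = bg_fun(.data$cycle_time_h),
      mo2 = (-.data$slope * chamber$effective_volume - .data$background_rate) /
        body_mass,
      flag_short = .data$n_samples < 3,
      flag_low_r2 = is.na(.data$r2) | .data$r2 < r2_threshold,
      flag_saturation = .data$min_o2 / chamber$saturation_concentration * 100 <
        saturation_floor,
      flag_negative = !is.na(.data$mo2) & .data$mo2 < 0,
      accepted = !.data$flag_short & !.data$flag_low_r2 &
        !.data$flag_saturation & !.data$flag_negative
    ) %>%
    select(-"min_o2")

  attr(fits, "effective_volume") <- chamber$effective_volume
  attr(fits, "body_mass") <- body_mass
  attr(fits, "r2_threshold") <- r2_threshold
  attr(fits, "saturation_floor") <- saturation_floor
  class(fits) <- c("mo2_series", class(fits))
  fits
}

#' @export
print.mo2_series <- function(x, ...) {
  n_acc <- sum(x$accepted)
  cat(sprintf(
    "<mo2_series> %d cycles (%d accepted), %.1f h, V_eff = %.2f L\n",
    nrow(x), n_acc, max(x$cycle_time_h), attr(x, "effective_volume")
  ))
  NextMethod()
}
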