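# Escape kinematics from chase-video click tracks: per-event Euclidean
# displacement, frame-calibrated speed, size-relative speed, and the
# correlation of escape metrics with recovery metabolism.

#' Euclidean distance between two click points
#'
#' \deqn{d = \sqrt{\sum_i (p_{1i} - p_{2i})^2}}
#'
#' @param p1,p2 Numeric coordinate vectors of equal length (pixels).
#' @return Distance in pixels.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    abort("Points must have the same dimensionality.")
  }
  sqrt(sum((p1 - p2)^2))
}

#' Per-event escape speeds from a click track
#'
#' Consecutive click rows are paired in order as the before/after positions
#' of each tail flip. Each event's speed is
#' \deqn{v = \frac{d}{\Delta f} \cdot \frac{fps}{px\_per\_cm}}
#' with `d` the Euclidean pixel displacement and `df` the frame gap.
#' Zero-frame-gap events have undefined speed: they are flagged and excluded
#' from speed statistics, never silently dropped.
#'
#' @param track A click tibble (`frame`, `x`, `y`), e.g. from
#'   [read_chase_track()] or [simulate_chase_track()].
#' @param fps Frame rate, frames s^-1; defaults to the track's attribute.
#' @param px_per_cm Pixel calibration, px cm^-1; defaults to the track's
#'   attribute.
#' @return A tibble per event: `event`, `frame_start`, `frame_gap`,
#'   `distance_px`, `speed_cm_s` (`NA` when flagged) and `flag_zero_gap`.
#' @export
escape_speeds <- function(track, fps = NULL, px_per_cm = NULL) {
  fps <- fps %||% attr(track, "fps") %||% 24
  px_per_cm <- px_per_cm %||% attr(track, "px_per_cm")
  if (is.null(px_per_cm)) abort("`px_per_cm` calibration is required.")
  if (fps <= 0 || px_per_cm <= 0) abort("`fps` and `px_per_cm` must be positive.")
  n <- nrow(track)
  if (n %% 2 != 0) {
    abort("Click track has an odd number of clicks; cannot pair events.")
  }
  if (n == 0) {
    return(tibble(
      event = integer(), frame_start = numeric(), frame_gap = numeric(),
      distance_px = numeric(), speed_cm_s = numeric(), flag_zero_gap = logical()
    ))
  }
  i1 <- seq(1, n, by = 2)
  i2 <- i1 + 1
  d_px <- sqrt((track$x[i2] - track$x[i1])^2 + (track$y[i2] - track$y[i1])^2)
  gap <- track$frame[i2] - track$frame[i1]
  tibble(
    event = seq_along(i1),
    frame_start = track$frame[i1],
    frame_gap = gap,
    distance_px = d_px,
    speed_cm_s = ifelse(gap > 0, d_px / gap * fps / px_per_cm, NA_real_),
    flag_zero_gap = gap == 0
  )
}

#' Size-relative escape speed
#'
#' @param speed Speed, cm s^-1.
#' @param carapace_length Carapace length, cm (> 0).
#' @return Speed in carapace lengths per second.
#' @export
relative_speed <- function(speed, carapace_length) {
  if (any(carapace_length <= 0)) abort("`carapace_length` must be positive.")
  speed / carapace_length
}

#' Trial-level escape summary
#'
#' Counts tail flips and summarises event speeds (mean and maximum, plus
#' size-relative versions when a carapace length is given). Zero-frame-gap
#' events count towards `total_escapes` but not towards speed statistics.
#'
#' @inheritParams escape_speeds
#' @param carapace_length Optional carapace length, cm.
#' @return A one-row tibble: `total_escapes`, `n_speed_events`,
#'   `mean_speed_cm_s`, `max_speed_cm_s`, `mean_relative_speed`,
#'   `max_relative_speed`, `n_flagged_zero_gap`.
#' @export
escape_summary <- function(track, fps = NULL, px_per_cm = NULL,
                           carapace_length = NULL) {
  ev <- escape_speeds(track, fps = fps, px_per_cm = px_per_cm)
  ok <- ev$speed_cm_s[!ev$flag_zero_gap]
  mean_sp <- if (length(ok) > 0) mean(ok) else NA_real_
  max_sp <- if (length(ok) > 0) max(ok) else NA_real_
  tibble(
    total_escapes = nrow(ev),
    n_speed_events = length(ok),
    mean_speed_cm_s = mean_sp,
    max_speed_cm_s = max_sp,
    mean_relative_speed = if (!is.null(carapace_length)) {
      relative_speed(mean_sp, carapace_length)
    } else {
      NA_real_
    },
    max_relative_speed = if (!is.null(carapace_length)) {
      relative_speed(max_sp, carapace_length)
    } else {
      NA_real_
    },
    n_flagged_zero_gap = sum(ev$flag_zero_gap)
  )
}

#' Correlate a per-animal escape metric with EPOC
#'
#' Pearson correlation between an escape metric and EPOC, with a
#' Shapiro-Wilk normality gate reported per variable. When either variable
#' fails the gate the correlation is still computed but flagged.
#'
#' @param data Per-animal table.
#' @param metric,epoc Column names (strings) of the escape metric and EPOC.
#' @param alpha Normality-gate significance level.
#' @return A one-row tibble: `r`, `p_value`, `n`, `shapiro_p_metric`,
#'   `shapiro_p_epoc`, `normality_ok`.
#' @export
correlate_with_epoc <- function(data, metric, epoc = "epoc", alpha = 0.05) {
  x <- data[[metric]]
  y <- data[[epoc]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance in one of the variables; correlation undefined.")
  }
  sw_x <- shapiro.test(x)$p.value
  sw_y <- shapiro.test(y)$p.value
  ct <- cor.test(x, y, method = "pearson")
  out <- tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x),
    shapiro_p_metric = sw_x,
    shapiro_p_epoc = sw_y,
    normality_ok = sw_x >= alpha & sw_y >= alpha
  )
  if (!out$normality_ok) {
    warn("Normality gate failed for at least one variable; Pearson r flagged.")
  }
  out
}
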