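# Shared builders for hand-made series and tracks.

# Minimal accepted MO2 series from explicit times (h) and values.
make_series <- function(cycle_time_h, mo2, accepted = TRUE) {
  tibble::tibble(
    cycle = seq_along(cycle_time_h),
    cycle_time_h = cycle_time_h,
    mo2 = mo2,
    accepted = rep_len(accepted, length(cycle_time_h))
  )
}

# Brute-force oracle for the recovery-time rule: scan cycles in time order
# and return the time of the k-th one strictly below the threshold.
recovery_time_oracle <- function(times, values, threshold, k = 3) {
  ord <- order(times)
  times <- times[ord]
  values <- values[ord]
  hits <- 0
  for (i in seq_along(values)) {
    if (values[i] < threshold) {
      hits <- hits + 1
      if (hits == k) return(times[i])
    }
  }
  NA_real_
}

# Sort-based oracle for the lowest-decile SMR estimator.
smr_oracle <- function(values, q = 0.1) {
  k <- ceiling(q * length(values))
  mean(sort(values)[seq_len(k)])
}

# A linear two-phase trace written to a temp CSV; returns the path.
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, progress = FALSE)
  path
}
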