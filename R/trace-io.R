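# Readers and writers for the plain-text dialects used throughout:
# comma-separated, mandatory header row, "." decimal. Readers validate and
# reject inconsistent input (with row numbers); they never silently repair.

trace_required_cols <- c("time_s", "o2")
track_required_cols <- c("frame", "x", "y")

read_csv_strict <- function(path, required, what) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot parse ", what, " file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (nrow(df) == 0) abort(paste0("No samples: ", what, " file ", path, " is empty."))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      what, " file ", path, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Unparseable values in ", path, " at row(s) ",
      paste(unique(probs$row), collapse = ", ")
    ))
  }
  df
}

#' Assign measure/flush phases from a fixed schedule
#'
#' Labels each sample of a trace by where it falls in the repeating
#' measure-then-flush cycle (cycle period = `measure_s + flush_s`, first
#' measure phase starting at time 0), and numbers the measure cycles.
#'
#' @param trace A tibble with a `time_s` column.
#' @param measure_s,flush_s Measure and flush phase durations, s.
#' @return The trace with `phase` and `cycle` columns set.
#' @export
assign_phases <- function(trace, measure_s = 360, flush_s = 480) {
  if (measure_s <= 0 || flush_s <= 0) {
    abort("Schedule durations must be positive.")
  }
  period <- measure_s + flush_s
  offset <- trace$time_s %% period
  trace$phase <- ifelse(offset < measure_s, "measure", "flush")
  trace$cycle <- ifelse(
    trace$phase == "measure",
    as.integer(trace$time_s %/% period) + 1L,
    NA_integer_
  )
  trace
}

#' Read an oxygen trace from CSV
#'
#' Expects at least `time_s` and `o2` columns (`temperature`, `channel_id`,
#' `phase`, `cycle` are carried through when present). If the file has no
#' `phase` column a measure/flush `schedule` must be supplied and phases are
#' assigned with [assign_phases()].
#'
#' @param path CSV file path.
#' @param schedule Optional list with `measure_s` and `flush_s` (seconds).
#' @param tolerance Relative tolerance on the nominal sample spacing before a
#'   gap is reported, as a multiple of the median spacing.
#' @return An oxygen-trace tibble.
#' @export
read_trace <- function(path, schedule = NULL, tolerance = 3) {
  df <- read_csv_strict(path, trace_required_cols, "trace")
  if (!is.numeric(df$time_s) || !is.numeric(df$o2)) {
    abort(paste0("Columns time_s and o2 in ", path, " must be numeric."))
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      "Non-monotone time in ", path, " at row(s) ",
      paste(head(bad + 1, 5), collapse = ", ")
    ))
  }
  if (!"phase" %in% names(df)) {
    if (is.null(schedule)) {
      abort("Trace has no phase column; supply schedule = list(measure_s=, flush_s=).")
    }
    df <- assign_phases(df, schedule$measure_s, schedule$flush_s)
  } else {
    bad_phase <- which(!df$phase %in% c("measure", "flush"))
    if (length(bad_phase) > 0) {
      abort(paste0(
        "Unknown phase label in ", path, " at row(s) ",
        paste(head(bad_phase, 5), collapse = ", ")
      ))
    }
    if (!"cycle" %in% names(df)) {
      # number measure phases by runs of consecutive measure samples
      is_m <- df$phase == "measure"
      starts <- is_m & !c(FALSE, is_m[-length(is_m)])
      df$cycle <- ifelse(is_m, cumsum(starts), NA_integer_)
    }
  }
  short <- df %>%
    filter(.data$phase == "measure") %>%
    dplyr::count(.data$cycle) %>%
    filter(.data$n < 3)
  if (nrow(short) > 0) {
    warn(paste0(
      "Measure cycle(s) with fewer than 3 samples: ",
      paste(short$cycle, collapse = ", ")
    ))
  }
  as_tibble(df)
}

#' Read a chase click track from CSV
#'
#' Rows are individual mouse clicks (`frame`, `x`, `y`); consecutive rows are
#' paired in order as the before/after clicks of each tail flip.
#'
#' @param path CSV file path.
#' @param fps Frame rate, frames s^-1 (default 24).
#' @param px_per_cm Pixel-to-centimetre calibration.
#' @return A click tibble with `fps` and `px_per_cm` attributes.
#' @export
read_chase_track <- function(path, fps = 24, px_per_cm = 10) {
  if (fps <= 0 || px_per_cm <= 0) abort("`fps` and `px_per_cm` must be positive.")
  df <- read_csv_strict(path, track_required_cols, "chase track")
  bad <- which(diff(df$frame) < 0)
  if (length(bad) > 0) {
    abort(paste0(
      "Decreasing frame numbers in ", path, " at row ", bad[1] + 1
    ))
  }
  if (nrow(df) %% 2 != 0) {
    abort(paste0(
      "Odd number of clicks (", nrow(df), ") in ", path,
      ": every tail flip needs a before and an after click."
    ))
  }
  out <- as_tibble(df[, track_required_cols])
  attr(out, "fps") <- fps
  attr(out, "px_per_cm") <- px_per_cm
  out
}

#' Read an animal metadata table from CSV
#'
#' Requires `animal_id`, `species`, `body_mass` (kg); `body_volume` (L) is
#' derived from `body_mass / body_density` where absent.
#'
#' @param path CSV file path.
#' @param body_density Default body density, g mL^-1, used to fill missing
#'   body volumes.
#' @return A tibble of animal records.
#' @export
read_animal_records <- function(path, body_density = 1.12) {
  df <- read_csv_strict(path, c("animal_id", "species", "body_mass"), "animal metadata")
  bad <- which(!is.finite(df$body_mass) | df$body_mass <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      "Non-positive body_mass in ", path, " at row(s) ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  if (!"body_volume" %in% names(df)) df$body_volume <- NA_real_
  df$body_volume <- ifelse(
    is.na(df$body_volume), df$body_mass / body_density, df$body_volume
  )
  as_tibble(df)
}

#' Write a set of result tables to CSV files
#'
#' Writes each named tibble in `tables` to `<dir>/<name>.csv` with a fixed
#' column order and UTF-8 encoding, so that reading them back with
#' [read_results()] round-trips.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, dir) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a fully named list.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(tables, function(tbl, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tbl, p, progress = FALSE)
    p
  })
  invisible(paths)
}

#' Read back result tables written by [write_results()]
#'
#' @param dir Directory containing `.csv` files.
#' @return Named list of tibbles.
#' @export
read_results <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("No result tables found in ", dir))
  out <- purrr::map(files, readr::read_csv,
    show_col_types = FALSE, progress = FALSE
  )
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Read a YAML pipeline/scenario configuration
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  yaml::read_yaml(path)
}
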