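# Readers and writers for the package's delimited-text formats: motion and
# slow-channel CSVs, annotation CSVs, per-period prediction CSVs, and the
# YAML/JSON run configuration. All files are comma-separated UTF-8 with a
# mandatory header row and '.' decimal separator; time is seconds from
# record start.

MOTION_COLS <- c("time", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
SLOW_COLS <- c("time", "pressure", "temperature", "light")
ACTIVITY_LEVELS <- c("swim", "drift", "unknown")
TETHER_LEVELS <- c("taut", "slack", "unknown")

#' Construct and validate a tag record
#'
#' A tag record bundles the 100 Hz motion channels (triaxial accelerometer
#' in g, gyroscope in deg/s, magnetometer in arbitrary consistent units) and
#' the 1 Hz slow channels (pressure in dbar, temperature in deg C, light in
#' arbitrary units) of one deployment. The motion channels must share one
#' strictly increasing uniform time grid with step `1/fs_motion` (tolerance
#' 1e-6 s); the slow channels share a 1 Hz grid spanning the same interval
#' (within one sample); missing samples are an input error.
#'
#' @param motion tibble with columns `time, ax, ay, az, gx, gy, gz, mx, my,
#'   mz`.
#' @param slow tibble with columns `time, pressure, temperature, light`.
#' @param deployment_id deployment identifier (text).
#' @param fs_motion motion sampling rate in Hz (default 100).
#' @param fs_slow slow-channel sampling rate in Hz (default 1).
#' @return an object of class `jellytag_tag_record`.
#' @export
tag_record <- function(motion, slow, deployment_id = "deployment",
                       fs_motion = 100, fs_slow = 1) {
  motion <- as_tibble(motion)
  slow <- as_tibble(slow)
  check_columns(motion, MOTION_COLS, "motion")
  check_columns(slow, SLOW_COLS, "slow")
  check_grid(motion$time, 1 / fs_motion, "motion")
  if (nrow(slow) > 1L) check_grid(slow$time, 1 / fs_slow, "slow")
  if (anyNA(motion) || anyNA(slow)) {
    abort_jt("missing samples in tag record (gaps are an input error)",
             "grid_error")
  }
  span_m <- range(motion$time)
  span_s <- range(slow$time)
  if (abs(span_s[1] - span_m[1]) > 1 / fs_slow + 1e-6 ||
      abs(span_s[2] - span_m[2]) > 1 / fs_slow + 1e-6) {
    abort_jt("slow-channel grid does not span the motion grid (within one sample)",
             "grid_error")
  }
  structure(
    list(motion = motion[MOTION_COLS], slow = slow[SLOW_COLS],
         deployment_id = deployment_id,
         fs_motion = fs_motion, fs_slow = fs_slow),
    class = "jellytag_tag_record"
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_jt(sprintf("%s table lacks column(s): %s", what,
                     paste(missing, collapse = ", ")),
             "format_error")
  }
  invisible(df)
}

check_grid <- function(time, step, what, tol = 1e-6) {
  if (length(time) > 1L) {
    d <- diff(time)
    if (any(d <= 0) || any(abs(d - step) > tol)) {
      abort_jt(sprintf(
        "%s time grid is not strictly increasing with constant step %g s",
        what, step), "grid_error")
    }
  }
  invisible(time)
}

#' @export
print.jellytag_tag_record <- function(x, ...) {
  cat(sprintf(
    "<jellytag_tag_record> '%s': %d motion samples @ %g Hz (%.1f s), %d slow samples\n",
    x$deployment_id, nrow(x$motion), x$fs_motion,
    nrow(x$motion) / x$fs_motion, nrow(x$slow)))
  invisible(x)
}

#' Read a tag record from motion and slow-channel CSVs
#'
#' @param path_motion CSV with header `time, ax, ay, az, gx, gy, gz, mx, my,
#'   mz`.
#' @param path_slow CSV with header `time, pressure, temperature, light`.
#' @param deployment_id deployment identifier; defaults to the motion file
#'   stem. If a metadata sidecar `<path_motion>.json` exists, its
#'   `deployment_id` and sampling rates take precedence.
#' @inheritParams tag_record
#' @return a validated [tag_record()].
#' @export
read_tag_record <- function(path_motion, path_slow, deployment_id = NULL,
                            fs_motion = 100, fs_slow = 1) {
  motion <- read_jt_csv(path_motion)
  slow <- read_jt_csv(path_slow)
  sidecar <- paste0(path_motion, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    deployment_id <- meta$deployment_id %||% deployment_id
    fs_motion <- meta$fs_motion %||% fs_motion
    fs_slow <- meta$fs_slow %||% fs_slow
  }
  if (is.null(deployment_id)) {
    deployment_id <- sub("\\.[^.]+$", "", basename(path_motion))
  }
  tag_record(motion, slow, deployment_id = deployment_id,
             fs_motion = fs_motion, fs_slow = fs_slow)
}

read_jt_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  locale = readr::locale(decimal_mark = "."))
}

#' Write a tag record to motion and slow-channel CSVs
#'
#' Writes the two channel tables and a small JSON metadata sidecar
#' (`<path_motion>.json`) holding the deployment id, sampling rates and an
#' optional wall-clock start time, so that [read_tag_record()] round-trips.
#'
#' @param record a [tag_record()].
#' @param path_motion,path_slow output CSV paths.
#' @param start_time optional wall-clock start (ISO-8601 text), stored once
#'   in the sidecar; within the tables, time is seconds from record start.
#' @return `record`, invisibly.
#' @export
write_tag_record <- function(record, path_motion, path_slow,
                             start_time = NULL) {
  stopifnot(inherits(record, "jellytag_tag_record"))
  readr::write_csv(record$motion, path_motion, progress = FALSE)
  readr::write_csv(record$slow, path_slow, progress = FALSE)
  meta <- list(deployment_id = record$deployment_id,
               fs_motion = record$fs_motion, fs_slow = record$fs_slow)
  if (!is.null(start_time)) meta$start_time <- start_time
  jsonlite::write_json(meta, paste0(path_motion, ".json"), auto_unbox = TRUE)
  invisible(record)
}

#' Construct and validate an annotation track
#'
#' Per-second behavioral annotations as half-open intervals
#' `[start_s, end_s)`, each labeled with an activity (`swim`, `drift`,
#' `unknown`) and a tether state (`taut`, `slack`, `unknown`). Intervals
#' must be non-overlapping; they are sorted by start time.
#'
#' @param intervals tibble with columns `start_s, end_s, activity, tether`.
#' @param deployment_id deployment identifier.
#' @return a tibble of class `jellytag_annotations` with attribute
#'   `deployment_id`.
#' @export
annotation_track <- function(intervals, deployment_id = "deployment") {
  x <- as_tibble(intervals)
  check_columns(x, c("start_s", "end_s", "activity", "tether"), "annotation")
  bad_act <- setdiff(unique(x$activity), ACTIVITY_LEVELS)
  bad_tet <- setdiff(unique(x$tether), TETHER_LEVELS)
  if (length(bad_act) || length(bad_tet)) {
    abort_jt(sprintf("unknown annotation token(s): %s",
                     paste(c(bad_act, bad_tet), collapse = ", ")),
             "validation_error")
  }
  if (any(x$end_s <= x$start_s)) {
    abort_jt("annotation intervals must have end_s > start_s",
             "validation_error")
  }
  x <- arrange(x, .data$start_s)
  if (nrow(x) > 1L && any(x$start_s[-1L] < x$end_s[-nrow(x)])) {
    abort_jt("annotation intervals overlap", "validation_error")
  }
  structure(x[c("start_s", "end_s", "activity", "tether")],
            deployment_id = deployment_id,
            class = c("jellytag_annotations", class(x)))
}

#' Read / write annotation tracks
#'
#' @param path CSV with columns `start_s, end_s, activity, tether`.
#' @param deployment_id deployment identifier (defaults to the file stem).
#' @return [read_annotations()] returns a validated [annotation_track()];
#'   `write_annotations()` returns its input invisibly.
#' @export
read_annotations <- function(path, deployment_id = NULL) {
  x <- read_jt_csv(path)
  annotation_track(
    x, deployment_id = deployment_id %||% sub("\\.[^.]+$", "", basename(path)))
}

#' @rdname read_annotations
#' @param annotations an [annotation_track()].
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(as_tibble(annotations), path, progress = FALSE)
  invisible(annotations)
}

PREDICTION_COLS <- c("deployment_id", "period_id", "start_s", "end_s",
                     "tether_label", "tether_posterior",
                     "activity_label", "activity_posterior")

#' Write / read classified periods
#'
#' One row per period with the fixed column order `deployment_id, period_id,
#' start_s, end_s, tether_label, tether_posterior, activity_label,
#' activity_posterior`; posteriors are written with six decimals. Zero
#' periods yield a header-only file.
#'
#' @param periods tibble carrying (at least) the prediction columns.
#' @param path output CSV path.
#' @return the written tibble (in output column order), invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(periods, path) {
  x <- as_tibble(periods)
  check_columns(x, PREDICTION_COLS, "prediction")
  x <- x[PREDICTION_COLS]
  x$tether_posterior <- round(x$tether_posterior, 6)
  x$activity_posterior <- round(x$activity_posterior, 6)
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  x <- read_jt_csv(path)
  check_columns(x, PREDICTION_COLS, "prediction")
  x
}

#' Read / write a run configuration
#'
#' The run configuration is a single YAML (or JSON) file whose keys are the
#' tunables of the pipeline: the simulator settings (see [sim_config()]) and
#' the analysis settings (`cutoff_hz`, `declination_deg`, `search_band_hz`,
#' `rpf_signal`, `ridge`, `k_outer`, `k_inner`, `min_delta`).
#'
#' @param path YAML or JSON file path (by extension).
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname read_run_config
#' @param config named list of tunables.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
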