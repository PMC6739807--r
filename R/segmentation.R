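# Pulse-cycle segmentation: estimate each deployment's representative pulse
# frequency from the DCT of the dynamic acceleration, then cut annotated
# runs into consecutive non-overlapping periods one pulse cycle long.

#' Representative pulse frequency (RPF)
#'
#' Computes the type-II discrete cosine transform of a full-deployment
#' dynamic-acceleration signal and returns the frequency of the maximum
#' absolute coefficient within a search band. DCT bin k (0-based) maps to
#' frequency `k * fs / (2 * N)`. The default 0.05-5 Hz band excludes DC and
#' slow drift leakage, which would otherwise dominate the argmax.
#'
#' The estimate is flagged low-confidence (attribute `low_confidence`) when
#' the winning coefficient is less than 3 times the median absolute
#' coefficient in the band, as happens for noise-like signals with no
#' dominant pulse.
#'
#' @param x numeric series (typically |DA_x|; see `rpf_signal` in the run
#'   configuration for the PDBA/ODBA alternatives).
#' @param fs sampling rate (Hz); the signal should be at least 10 s long.
#' @param search_band numeric length-2, Hz, within `(0, fs / 2)`.
#' @return the RPF in Hz, with attributes `bin_hz` (bin width),
#'   `low_confidence` (logical) and `peak_ratio` (max / band median).
#' @export
representative_pulse_frequency <- function(x, fs, search_band = c(0.05, 5)) {
  stopifnot(length(search_band) == 2L, search_band[1] < search_band[2])
  if (length(x) < 10 * fs) {
    abort_jt("signal shorter than 10 s; too short for a stable RPF",
             "length_error")
  }
  if (search_band[2] > fs / 2 || search_band[1] <= 0) {
    abort_jt("search band must lie within (0, fs / 2)", "band_error")
  }
  co <- abs(dct_ii(x))
  f <- dct_freqs(length(x), fs)
  in_band <- f >= search_band[1] & f <= search_band[2]
  if (!any(in_band)) {
    abort_jt("no DCT bins inside the search band", "band_error")
  }
  cb <- co[in_band]
  fb <- f[in_band]
  k <- which.max(cb)
  ratio <- cb[k] / stats::median(cb)
  structure(fb[k],
            bin_hz = fs / (2 * length(x)),
            low_confidence = ratio < 3,
            peak_ratio = ratio)
}

#' Cut annotated data into pulse-cycle periods
#'
#' Splits each maximal run of seconds sharing an (activity, tether) label
#' into consecutive, non-overlapping windows of one representative pulse
#' cycle (`round(fs / rpf)` samples; identical for every period of the
#' deployment). Runs shorter than one period contribute nothing, and the
#' trailing partial window of each run is discarded. Periods inherit the
#' run's labels, with the tether state mapped to `influenced` (taut),
#' `uninfluenced` (slack) or `unknown`; seconds not covered by any
#' annotation interval are treated as unknown/unknown. Periods with an
#' unknown label are emitted (so they can still be classified) but flagged
#' ineligible for training.
#'
#' @param annotations an [annotation_track()] (or `NULL` to segment the
#'   whole record as unannotated).
#' @param record a [tag_record()].
#' @param rpf representative pulse frequency in Hz (see
#'   [representative_pulse_frequency()]).
#' @param source data provenance label, `"laboratory"` or `"in_situ"`.
#' @return a tibble with one row per period: `deployment_id, period_id,
#'   start_s, end_s, start_sample, end_sample, activity, tether, source,
#'   eligible`.
#' @export
segment_periods <- function(annotations, record, rpf,
                            source = c("in_situ", "laboratory")) {
  stopifnot(inherits(record, "jellytag_tag_record"))
  source <- match.arg(source)
  if (!is.numeric(rpf) || rpf <= 0) {
    abort_jt("rpf must be a positive frequency in Hz", "validation_error")
  }
  fs <- record$fs_motion
  n <- nrow(record$motion)
  n_s <- floor(n / fs)
  period_samples <- as.integer(round(fs / rpf))

  # rasterize annotations onto the whole-second grid of the record
  activity <- rep("unknown", n_s)
  tether <- rep("unknown", n_s)
  if (!is.null(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      lo <- max(0, floor(annotations$start_s[i]))
      hi <- min(n_s, ceiling(annotations$end_s[i]))
      if (hi > lo) {
        idx <- (lo + 1):hi
        activity[idx] <- annotations$activity[i]
        tether[idx] <- annotations$tether[i]
      }
    }
  }
  key <- paste(activity, tether)
  run_id <- c(0L, cumsum(key[-1L] != key[-n_s]))
  runs <- tibble(second = 0:(n_s - 1), activity = activity,
                 tether = tether, run = run_id) |>
    group_by(.data$run) |>
    summarise(start_s = min(.data$second), end_s = max(.data$second) + 1,
              activity = .data$activity[1], tether = .data$tether[1],
              .groups = "drop")

  out <- purrr::pmap(runs, function(run, start_s, end_s, activity, tether) {
    run_samples <- (end_s - start_s) * fs
    k <- floor(run_samples / period_samples)
    if (k < 1) return(NULL)
    j <- seq_len(k)
    first <- start_s * fs + (j - 1L) * period_samples + 1L
    tibble(
      start_sample = as.integer(first),
      end_sample = as.integer(first + period_samples - 1L),
      activity = activity,
      tether = c(taut = "influenced", slack = "uninfluenced",
                 unknown = "unknown")[[tether]]
    )
  }) |> list_rbind()

  if (nrow(out) == 0L) {
    out <- tibble(start_sample = integer(), end_sample = integer(),
                  activity = character(), tether = character())
  }
  out |>
    mutate(
      deployment_id = record$deployment_id,
      period_id = row_number(),
      start_s = (.data$start_sample - 1L) / fs,
      end_s = .data$end_sample / fs,
      source = source,
      eligible = .data$activity != "unknown" & .data$tether != "unknown"
    ) |>
    select("deployment_id", "period_id", "start_s", "end_s",
           "start_sample", "end_sample", "activity", "tether",
           "source", "eligible")
}
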