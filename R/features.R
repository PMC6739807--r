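# Per-period featurization: the 45-feature accelerometer + gyroscope
# catalog, plus the normalized-ODBA summaries used by the baseline
# classifier and the statistical comparisons.

#' The 45-feature catalog
#'
#' Enumerates the per-period features: for each of the four base
#' accelerometer signals (|DA_x| and PDBA, both deployment-normalized, and
#' the x-axis and y/z-norm jerk) the maximum, mean and s.d.; Gini sparsity
#' of the |DA_x| and PDBA magnitude spectra; spectral energies of |DA_x| in
#' 0.2-1.0 Hz, 1-8 Hz and above 8 Hz and of PDBA in 0.2-1.0 Hz and 1-8 Hz
#' (the >8 Hz PDBA band is excluded as redundant with |DA_x|); peak counts
#' of |DA_x| and PDBA; the correlation between the y and z axes of DA; and
#' the mean of the x-y and x-z correlations (23 features). The gyroscope
#' template is identical with |AV_x|, PAV and angular acceleration
#' substituted, except that the >8 Hz band is excluded (22 features).
#'
#' @return a tibble with columns `feature`, `sensor` (`accel`/`gyro`) and
#'   `group`.
#' @export
feature_catalog <- function() {
  stat3 <- function(base) paste0(base, c("_max", "_mean", "_sd"))
  accel <- tibble::tibble(
    feature = c(
      stat3("dax_norm"), stat3("pdba_norm"),
      stat3("jerk_x"), stat3("jerk_yz"),
      "dax_spec_gini", "pdba_spec_gini",
      "dax_energy_pulse", "dax_energy_mid", "dax_energy_high",
      "pdba_energy_pulse", "pdba_energy_mid",
      "dax_peak_count", "pdba_peak_count",
      "da_yz_corr", "da_x_yz_corr_mean"
    ),
    sensor = "accel",
    group = c(rep("stat", 12), rep("gini", 2), rep("energy", 5),
              rep("peaks", 2), rep("corr", 2))
  )
  gyro <- tibble::tibble(
    feature = c(
      stat3("avx"), stat3("pav"),
      stat3("angacc_x"), stat3("angacc_yz"),
      "avx_spec_gini", "pav_spec_gini",
      "avx_energy_pulse", "avx_energy_mid",
      "pav_energy_pulse", "pav_energy_mid",
      "avx_peak_count", "pav_peak_count",
      "av_yz_corr", "av_x_yz_corr_mean"
    ),
    sensor = "gyro",
    group = c(rep("stat", 12), rep("gini", 2), rep("energy", 4),
              rep("peaks", 2), rep("corr", 2))
  )
  dplyr::bind_rows(accel, gyro)
}

#' Gini index of a nonnegative vector
#'
#' Sparsity measure in `[0, 1]`: 0 for a uniform vector, `1 - 1/N` for a
#' vector supported on a single entry. Computed as
#' `G = 1 - 2 * sum_k (v_(k) / ||v||_1) * ((N - k + 0.5) / N)` over the
#' ascending sort `v_(k)`.
#'
#' @param v nonnegative numeric vector. An all-zero vector is degenerate:
#'   the index is returned as 0 with attribute `degenerate = TRUE`.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' gini_index(c(1, 1, 1, 1))  # 0
#' gini_index(c(0, 0, 0, 1))  # 0.75
gini_index <- function(v) {
  stopifnot(is.numeric(v), length(v) > 0L)
  if (any(v < 0)) abort_jt("gini_index requires a nonnegative vector",
                           "validation_error")
  s <- sum(v)
  if (s == 0) return(structure(0, degenerate = TRUE))
  vs <- sort(v)
  N <- length(v)
  k <- seq_len(N)
  1 - 2 * sum((vs / s) * ((N - k + 0.5) / N))
}

# Magnitude spectrum of the unwindowed, mean-retained signal; bins at
# k * fs / N for k = 0 .. N-1. Only bins strictly below fs/2 are used.
magnitude_spectrum <- function(x, fs) {
  N <- length(x)
  keep <- 0:(ceiling(N / 2) - 1L)
  list(freq = keep * fs / N, mag = Mod(fft(x))[keep + 1L], n = N)
}

#' Band spectral energy
#'
#' Sum of squared magnitude-spectrum bins with `f_lo <= f < f_hi`, divided
#' by the signal length so energies are comparable across deployments with
#' different period durations. The spectrum is the unwindowed discrete
#' Fourier transform of the mean-retained signal; only bins below the
#' Nyquist frequency are counted, so the band partition
#' `{[0, 0.2), [0.2, 1), [1, 8), [8, fs/2)}` sums to the total.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param f_lo,f_hi band edges in Hz, `f_lo < f_hi <= fs / 2`.
#' @return nonnegative energy; 0 with attribute `empty_band = TRUE` when no
#'   bin falls in the band (very short periods).
#' @export
spectral_energy <- function(x, fs, f_lo, f_hi) {
  stopifnot(f_lo < f_hi, f_hi <= fs / 2 + 1e-12)
  sp <- magnitude_spectrum(x, fs)
  sel <- sp$freq >= f_lo & sp$freq < f_hi
  if (!any(sel)) return(structure(0, empty_band = TRUE))
  sum(sp$mag[sel]^2) / sp$n
}

#' Count peaks in a series
#'
#' Number of strict local maxima at least `min_height` high and separated by
#' at least `min_separation_s` seconds. Candidate maxima are accepted in
#' decreasing height order, discarding any candidate closer than the
#' minimum separation to an already accepted peak. Plateau maxima count
#' once (the first sample of the plateau).
#'
#' @param x numeric series.
#' @param min_height minimum peak height (same units as `x`).
#' @param min_separation_s minimum separation between retained peaks (s).
#' @param fs sampling rate (Hz).
#' @return integer count.
#' @export
count_peaks <- function(x, min_height, min_separation_s, fs) {
  stopifnot(min_separation_s > 0, fs > 0)
  n <- length(x)
  if (n < 3L) return(0L)
  # strict rise before, fall (or plateau then fall) after
  rise <- diff(x) > 0
  fall <- diff(x) < 0
  # carry "last move was a rise" across plateaus
  state <- rep(NA, n - 1L)
  state[rise] <- TRUE
  state[fall] <- FALSE
  prev_rise <- rep(FALSE, n)
  last <- FALSE
  for (i in seq_len(n - 1L)) {
    if (!is.na(state[i])) last <- state[i]
    prev_rise[i + 1L] <- last
  }
  cand <- which(prev_rise[-n] & fall) # position i: rise up to i, fall after
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(0L)
  min_gap <- min_separation_s * fs
  cand <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  length(kept)
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

# The 45 features of one period given its slice of the body signals.
featurize_slice <- function(sl, fs, rpf, peak_sep_frac = 0.25) {
  stat3 <- function(v) c(max(v), mean(v), sd(v))
  sep <- peak_sep_frac / rpf
  band <- function(v, lo, hi) as.numeric(spectral_energy(v, fs, lo, hi))
  vals <- c(
    stat3(sl$dax_abs_norm), stat3(sl$pdba_norm),
    stat3(sl$jerk_x_abs), stat3(sl$jerk_yz_norm),
    as.numeric(gini_index(magnitude_spectrum(sl$dax_abs_norm, fs)$mag)),
    as.numeric(gini_index(magnitude_spectrum(sl$pdba_norm, fs)$mag)),
    band(sl$dax_abs_norm, 0.2, 1), band(sl$dax_abs_norm, 1, 8),
    band(sl$dax_abs_norm, 8, fs / 2),
    band(sl$pdba_norm, 0.2, 1), band(sl$pdba_norm, 1, 8),
    count_peaks(sl$dax_abs_norm, mean(sl$dax_abs_norm), sep, fs),
    count_peaks(sl$pdba_norm, mean(sl$pdba_norm), sep, fs),
    safe_cor(sl$da_y, sl$da_z),
    mean(c(safe_cor(sl$da_x, sl$da_y), safe_cor(sl$da_x, sl$da_z))),
    stat3(sl$avx_abs), stat3(sl$pav),
    stat3(sl$angacc_x_abs), stat3(sl$angacc_yz_norm),
    as.numeric(gini_index(magnitude_spectrum(sl$avx_abs, fs)$mag)),
    as.numeric(gini_index(magnitude_spectrum(sl$pav, fs)$mag)),
    band(sl$avx_abs, 0.2, 1), band(sl$avx_abs, 1, 8),
    band(sl$pav, 0.2, 1), band(sl$pav, 1, 8),
    count_peaks(sl$avx_abs, mean(sl$avx_abs), sep, fs),
    count_peaks(sl$pav, mean(sl$pav), sep, fs),
    safe_cor(sl$av_y, sl$av_z),
    mean(c(safe_cor(sl$av_x, sl$av_y), safe_cor(sl$av_x, sl$av_z)))
  )
  stats::setNames(vals, feature_catalog()$feature)
}

#' Featurize segmented periods
#'
#' Computes the 45-feature catalog (see [feature_catalog()]) for every
#' period, plus the per-period mean and maximum of normalized ODBA (used by
#' the thresholding baseline and the behavioral statistics, not as
#' classification features) and, when an Euler series is supplied, the
#' per-period orientation change and a gimbal-exclusion flag (`TRUE` when
#' any sample of the period exceeds 70 deg absolute pitch).
#'
#' @param periods period table from [segment_periods()].
#' @param signals body-signal table from [body_signals()].
#' @param fs sampling rate (Hz).
#' @param rpf representative pulse frequency (Hz); sets the peak-detection
#'   separation `0.25 / rpf` s.
#' @param euler optional Euler series from [euler_angles()] on the same
#'   grid.
#' @return the period table with 45 feature columns, `odba_norm_mean`,
#'   `odba_norm_max`, and (if `euler` is given) `orientation_change` (deg,
#'   `NA` for gimbal-excluded periods) and `gimbal_excluded` appended.
#' @export
featurize_periods <- function(periods, signals, fs, rpf, euler = NULL) {
  if (nrow(periods) == 0L) {
    empty <- as_tibble(as.list(stats::setNames(
      rep(NA_real_, 45), feature_catalog()$feature)))[0, ]
    return(bind_cols(periods, empty,
                     tibble(odba_norm_mean = numeric(0),
                            odba_norm_max = numeric(0))))
  }
  if (any(periods$end_sample - periods$start_sample + 1L < 4L)) {
    abort_jt("periods must span at least 4 samples", "validation_error")
  }
  feats <- purrr::map2(
    periods$start_sample, periods$end_sample,
    function(a, b) {
      sl <- signals[a:b, ]
      v <- featurize_slice(sl, fs, rpf)
      c(v, odba_norm_mean = mean(sl$odba_norm),
        odba_norm_max = max(sl$odba_norm))
    }
  )
  fmat <- do.call(rbind, feats)
  out <- bind_cols(periods, as_tibble(as.data.frame(fmat)))
  if (!is.null(euler)) {
    oc <- purrr::map2(
      periods$start_sample, periods$end_sample,
      function(a, b) {
        ex <- euler[a:b, ]
        excl <- any(ex$gimbal | ex$degenerate)
        ang <- if (excl) NA_real_ else orientation_change(
          c(ex$heading[1], ex$pitch[1], ex$roll[1]),
          c(ex$heading[nrow(ex)], ex$pitch[nrow(ex)], ex$roll[nrow(ex)]))
        list(orientation_change = ang, gimbal_excluded = excl)
      }
    )
    out$orientation_change <- map_dbl(oc, "orientation_change")
    out$gimbal_excluded <- purrr::map_lgl(oc, "gimbal_excluded")
  }
  out
}

#' Process one deployment end to end
#'
#' Chains kinematic processing, RPF estimation, segmentation and
#' featurization for one (optionally annotated) deployment.
#'
#' @inheritParams segment_periods
#' @param record a [tag_record()].
#' @param annotations an [annotation_track()] or `NULL` (whole record
#'   treated as unannotated).
#' @param cutoff,declination see [process_kinematics()].
#' @param search_band RPF search band (Hz).
#' @param rpf_signal which dynamic-acceleration signal feeds the RPF
#'   estimate: the signed propulsion axis `"da_x"` (default), or the
#'   rectified `"dax_abs"`, `"pdba"`, `"odba"` variants. The signed axis is
#'   the default because rectification folds a zero-mean pulse train onto
#'   its even harmonics, which can displace the spectral argmax from the
#'   true pulse rate.
#' @return a list of class `jellytag_processed` with `features` (the
#'   featurized period table), `rpf`, `kin` (from [process_kinematics()])
#'   and `periods`.
#' @export
process_deployment <- function(record, annotations = NULL,
                               source = c("in_situ", "laboratory"),
                               cutoff = 0.2, declination = 0,
                               search_band = c(0.05, 5),
                               rpf_signal = c("da_x", "dax_abs", "pdba",
                                              "odba")) {
  source <- match.arg(source)
  rpf_signal <- match.arg(rpf_signal)
  kin <- process_kinematics(record, cutoff = cutoff,
                            declination = declination)
  rpf <- representative_pulse_frequency(kin$signals[[rpf_signal]],
                                        kin$fs, search_band)
  periods <- segment_periods(annotations, record, rpf, source = source)
  features <- featurize_periods(periods, kin$signals, kin$fs, rpf,
                                euler = kin$euler)
  structure(list(features = features, rpf = rpf, kin = kin,
                 periods = periods),
            class = "jellytag_processed")
}

#' Write a feature table to CSV
#'
#' One row per period: identification and label columns followed by the 45
#' catalog features and the normalized-ODBA summaries.
#'
#' @param features table from [featurize_periods()].
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(as_tibble(features), path, progress = FALSE)
  invisible(features)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- read_jt_csv(path)
  check_columns(x, feature_catalog()$feature, "feature")
  x
}
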