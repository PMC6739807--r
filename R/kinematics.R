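# Orientation and body-acceleration processing: linear-phase FIR smoothing,
# static/dynamic split, tilt-compensated Euler angles, per-period orientation
# change, circular statistics, and the derived body-signal channels that feed
# the featurization.

#' Zero-phase low-pass FIR smoothing
#'
#' Smooths a uniformly sampled signal with a Hamming windowed-sinc low-pass
#' filter, the standard way of separating gravity from animal-generated
#' acceleration on motion tags. The filter is linear-phase and the group
#' delay is compensated, so the output is time-aligned with the input; edges
#' are handled by reflection padding and the output has the same length as
#' the input.
#'
#' The filter order is `6 * fs / cutoff`, rounded up to an even order (odd
#' tap count), and the taps are rescaled to unit DC gain. At the default
#' 0.2 Hz cutoff and 100 Hz sampling this is a 3001-tap filter whose
#' transition band ends well below the 0.25-0.50 Hz pulse frequencies
#' typical of swimming medusae.
#'
#' @param x numeric vector, or a matrix / data frame whose columns are
#'   filtered independently.
#' @param fs sampling rate in Hz.
#' @param cutoff filter cut-off frequency in Hz; must satisfy
#'   `fs > 2 * cutoff`.
#' @return an object of the same shape as `x`, smoothed.
#' @export
#' @examples
#' t <- seq(0, 60, by = 0.01)
#' x <- sin(2 * pi * 0.01 * t) + sin(2 * pi * 5 * t)
#' y <- lowpass_fir(x, fs = 100, cutoff = 0.2)
lowpass_fir <- function(x, fs, cutoff = 0.2) {
  if (!is.null(dim(x))) {
    out <- apply(as.matrix(x), 2, lowpass_fir, fs = fs, cutoff = cutoff)
    if (is.data.frame(x)) out <- as_tibble(as.data.frame(out))
    return(out)
  }
  stopifnot(is.numeric(x), fs > 2 * cutoff)
  h <- fir_taps(fs, cutoff)
  half <- (length(h) - 1L) / 2L
  if (length(x) <= half + 1L) {
    abort_jt(
      sprintf("signal length %d is too short for a %d-tap filter",
              length(x), length(h)),
      "length_error"
    )
  }
  pad_l <- x[pmin(half + 1L, length(x)):2L]            # reflection, no repeat
  pad_r <- x[(length(x) - 1L):(length(x) - half)]
  y <- conv_fft(c(pad_l, x, pad_r), h)
  y[(2L * half + 1L):(2L * half + length(x))]
}

fir_taps <- function(fs, cutoff) {
  ord <- ceiling(6 * fs / cutoff / 2) * 2        # even order, odd tap count
  h <- signal::fir1(ord, cutoff / (fs / 2))      # Hamming windowed sinc
  as.numeric(h) / sum(h)                         # exact unit DC gain
}

#' Split acceleration into static and dynamic components
#'
#' Low-pass filters each accelerometer axis to recover the gravity (static)
#' component; the dynamic acceleration (DA) is the exact remainder, so
#' `static + dynamic` reproduces the input to machine precision.
#'
#' @param accel matrix or data frame with three columns (x, y, z) of specific
#'   force in g.
#' @inheritParams lowpass_fir
#' @return a list with tibbles `static` and `dynamic` (columns `x`, `y`, `z`).
#' @export
split_static_dynamic <- function(accel, fs, cutoff = 0.2) {
  a <- as.matrix(accel)
  stopifnot(ncol(a) == 3L)
  static <- apply(a, 2, lowpass_fir, fs = fs, cutoff = cutoff)
  dynamic <- a - static
  colnames(static) <- colnames(dynamic) <- c("x", "y", "z")
  list(static = as_tibble(as.data.frame(static)),
       dynamic = as_tibble(as.data.frame(dynamic)))
}

#' Tilt-compensated Euler angles from static acceleration and magnetometer
#'
#' Computes heading, pitch and roll from the smoothed (static) accelerometer
#' and smoothed magnetometer series. Pitch is `atan2(ax, sqrt(ay^2 + az^2))`
#' (positive pitch tilts the sensor x axis, the bell apex, upward), roll is
#' `atan2(ay, az)`, and heading is the compass bearing of the
#' tilt-compensated horizontal magnetic component, clockwise from magnetic
#' north in `[0, 360)`. No declination correction is applied; pass
#' `declination` to rotate headings to true north.
#'
#' Samples where the static-acceleration norm falls below 0.5 g are flagged
#' degenerate (`NA` angles) rather than raising an error; samples with
#' `|pitch| > 70` degrees are flagged for gimbal lock, where heading and roll
#' become ill-conditioned.
#'
#' @param static_accel n x 3 matrix / data frame of static acceleration (g).
#' @param mag n x 3 matrix / data frame of smoothed magnetometer readings,
#'   same grid.
#' @param declination heading offset in degrees added to the magnetic
#'   heading (default 0).
#' @param gimbal_limit absolute pitch (degrees) beyond which heading/roll are
#'   flagged (default 70).
#' @return a tibble with columns `heading`, `pitch`, `roll` (degrees),
#'   `gimbal` and `degenerate` (logical).
#' @export
euler_angles <- function(static_accel, mag, declination = 0,
                         gimbal_limit = 70) {
  a <- as.matrix(static_accel)
  m <- as.matrix(mag)
  stopifnot(ncol(a) == 3L, ncol(m) == 3L, nrow(a) == nrow(m))
  norm_a <- sqrt(rowSums(a^2))
  degenerate <- norm_a < 0.5
  pitch <- rad2deg(atan2(a[, 1], sqrt(a[, 2]^2 + a[, 3]^2)))
  roll <- rad2deg(atan2(a[, 2], a[, 3]))
  # de-rotate the magnetometer by roll then pitch to the horizontal plane
  p <- deg2rad(pitch); r <- deg2rad(roll)
  m1x <- m[, 1]
  m1y <- cos(r) * m[, 2] - sin(r) * m[, 3]
  m1z <- sin(r) * m[, 2] + cos(r) * m[, 3]
  mhx <- cos(p) * m1x - sin(p) * m1z
  mhy <- m1y
  heading <- wrap360(rad2deg(atan2(-mhy, mhx)) + declination)
  heading[degenerate] <- NA_real_
  pitch[degenerate] <- NA_real_
  roll[degenerate] <- NA_real_
  tibble(
    heading = heading,
    pitch = pitch,
    roll = wrap180(roll),
    gimbal = !degenerate & abs(pitch) > gimbal_limit,
    degenerate = degenerate
  )
}

#' Total rotation angle between two orientations
#'
#' Converts the differences in heading, pitch and roll between the start and
#' end of a period into a single non-negative rotation angle: the Euler
#' differences (heading wrapped to (-180, 180]) are composed into a rotation
#' matrix in the package's rotation order and the matrix rotation angle
#' `acos((trace - 1) / 2)` is returned, in `[0, 180]` degrees.
#'
#' @param start,end numeric length-3 vectors `(heading, pitch, roll)` in
#'   degrees, or n x 3 matrices / data frames for vectorized use.
#' @return rotation angle(s) in degrees, in `[0, 180]`.
#' @export
#' @examples
#' orientation_change(c(10, 0, 0), c(10, 0, 0))   # 0
#' orientation_change(c(0, 0, 0), c(180, 0, 0))   # 180
orientation_change <- function(start, end) {
  s <- if (is.null(dim(start))) matrix(start, ncol = 3) else as.matrix(start)
  e <- if (is.null(dim(end))) matrix(end, ncol = 3) else as.matrix(end)
  stopifnot(ncol(s) == 3L, ncol(e) == 3L, nrow(s) == nrow(e))
  dh <- wrap180(e[, 1] - s[, 1])
  dp <- e[, 2] - s[, 2]
  dr <- wrap180(e[, 3] - s[, 3])
  ent <- rotmat_entries(dh, dp, dr)
  tr <- ent$r11 + ent$r22 + ent$r33
  out <- rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
  if (is.null(dim(start)) && length(start) == 3L) out[[1]] else out
}

#' Circular mean and standard deviation
#'
#' Mean direction `atan2(sum(sin), sum(cos))` wrapped to `[0, 360)` and the
#' circular standard deviation `sqrt(-2 * log(Rbar))`, both in degrees. When
#' the resultant length is numerically zero (angles uniformly spread) the
#' mean direction is undefined and an error of class
#' `jellytag_undefined_mean` is raised.
#'
#' @param angles numeric vector of angles in degrees (any wrap).
#' @param na.rm drop `NA` angles first (default `TRUE`).
#' @return a list with elements `mean` and `sd`, both in degrees.
#' @export
circular_mean_sd <- function(angles, na.rm = TRUE) {
  if (na.rm) angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) {
    abort_jt("no angles supplied", "undefined_mean")
  }
  a <- deg2rad(angles)
  s <- mean(sin(a)); c <- mean(cos(a))
  rbar <- sqrt(s^2 + c^2)
  if (rbar < 1e-12) {
    abort_jt("resultant length ~ 0: circular mean is undefined",
             "undefined_mean")
  }
  list(mean = wrap360(rad2deg(atan2(s, c))),
       sd = rad2deg(sqrt(-2 * log(rbar))))
}

#' Derived body-motion signals
#'
#' Computes the nonnegative summary channels used throughout the analysis
#' from the dynamic acceleration and gyroscope series:
#'
#' * `dax_abs` (|DA_x|, propulsion axis), `pdba` (|DA_y| + |DA_z|, partial
#'   dynamic body acceleration) and `odba` (|DA_x| + |DA_y| + |DA_z|), plus
#'   `dax_abs_norm`, `pdba_norm`, `odba_norm` divided by their deployment
#'   means so individuals with different propulsive strength are comparable;
#' * `jerk_x_abs` and `jerk_yz_norm` (g/s), the forward first difference of
#'   DA scaled by `fs` (L2 norm over y, z; the last difference is repeated
#'   so lengths match);
#' * gyroscope analogues `avx_abs`, `pav` (L2 norm of the y and z angular
#'   velocities, deg/s) and angular accelerations `angacc_x_abs`,
#'   `angacc_yz_norm` (deg/s^2).
#'
#' The raw signed dynamic-acceleration and gyroscope axes are carried along
#' for the correlation features.
#'
#' @param dynamic n x 3 dynamic acceleration (g).
#' @param gyro n x 3 angular velocity (deg/s).
#' @param fs sampling rate (Hz).
#' @return a tibble of aligned signal columns, with the deployment means of
#'   |DA_x|, PDBA and ODBA attached as attribute `deployment_means`.
#' @export
body_signals <- function(dynamic, gyro, fs) {
  d <- as.matrix(dynamic)
  g <- as.matrix(gyro)
  stopifnot(ncol(d) == 3L, ncol(g) == 3L, nrow(d) == nrow(g))
  fdiff <- function(x) {
    n <- length(x)
    if (n < 2L) return(rep(0, n))
    dx <- (x[-1L] - x[-n]) * fs
    c(dx, dx[n - 1L])
  }
  dax_abs <- abs(d[, 1])
  pdba <- abs(d[, 2]) + abs(d[, 3])
  odba <- dax_abs + pdba
  means <- c(dax_abs = mean(dax_abs), pdba = mean(pdba), odba = mean(odba))
  if (any(means == 0)) {
    abort_jt("deployment mean of a body-acceleration signal is zero; cannot normalize",
             "normalization_error")
  }
  tib <- tibble(
    da_x = d[, 1], da_y = d[, 2], da_z = d[, 3],
    dax_abs = dax_abs, pdba = pdba, odba = odba,
    dax_abs_norm = dax_abs / means[["dax_abs"]],
    pdba_norm = pdba / means[["pdba"]],
    odba_norm = odba / means[["odba"]],
    jerk_x_abs = abs(fdiff(d[, 1])),
    jerk_yz_norm = sqrt(fdiff(d[, 2])^2 + fdiff(d[, 3])^2),
    av_x = g[, 1], av_y = g[, 2], av_z = g[, 3],
    avx_abs = abs(g[, 1]),
    pav = sqrt(g[, 2]^2 + g[, 3]^2),
    angacc_x_abs = abs(fdiff(g[, 1])),
    angacc_yz_norm = sqrt(fdiff(g[, 2])^2 + fdiff(g[, 3])^2)
  )
  attr(tib, "deployment_means") <- means
  tib
}

#' Full kinematic processing of a tag record
#'
#' Convenience wrapper chaining the smoothing, static/dynamic split, Euler
#' angle estimation and body-signal computation for one deployment.
#'
#' @param record a [tag_record()].
#' @param cutoff FIR cut-off in Hz (applied identically to accelerometer and
#'   magnetometer).
#' @param declination heading offset in degrees (see [euler_angles()]).
#' @return a list with `euler` (tibble), `signals` (tibble from
#'   [body_signals()]), `static`, `dynamic`, and `fs`.
#' @export
process_kinematics <- function(record, cutoff = 0.2, declination = 0) {
  stopifnot(inherits(record, "jellytag_tag_record"))
  fs <- record$fs_motion
  acc <- as.matrix(record$motion[, c("ax", "ay", "az")])
  mag <- as.matrix(record$motion[, c("mx", "my", "mz")])
  gyr <- as.matrix(record$motion[, c("gx", "gy", "gz")])
  sd_split <- split_static_dynamic(acc, fs, cutoff)
  mag_s <- lowpass_fir(mag, fs, cutoff)
  euler <- euler_angles(sd_split$static, mag_s, declination = declination)
  euler$time <- record$motion$time
  signals <- body_signals(sd_split$dynamic, gyr, fs)
  signals$time <- record$motion$time
  list(euler = euler, signals = signals,
       static = sd_split$static, dynamic = sd_split$dynamic, fs = fs)
}
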