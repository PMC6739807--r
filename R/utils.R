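# Internal numerical helpers: angle wrapping, FFT convolution, DCT-II,
# and the Euler-angle rotation model shared by the forward simulator and
# the orientation estimator.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[0, 360)`.
#' @export
wrap360 <- function(x) x %% 360

#' Wrap angles into (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `(-180, 180]`.
#' @export
wrap180 <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

abort_jt <- function(message, class, ...) {
  abort(message, class = c(paste0("jellytag_", class), "jellytag_error"), ...)
}

# Linear convolution via zero-padded FFTs (lengths padded to 2-3-5 smooth).
conv_fft <- function(a, b) {
  n <- length(a) + length(b) - 1L
  L <- stats::nextn(n, c(2, 3, 5))
  fa <- fft(c(a, numeric(L - length(a))))
  fb <- fft(c(b, numeric(L - length(b))))
  Re(fft(fa * fb, inverse = TRUE))[seq_len(n)] / L
}

# Orthodox DCT-II, X_k = sum_n x_n cos(pi (n + 1/2) k / N), via a 2N FFT.
dct_ii <- function(x) {
  N <- length(x)
  Y <- fft(c(x, rev(x)))
  Re(exp(-1i * pi * (0:(N - 1)) / (2 * N)) * Y[seq_len(N)]) / 2
}

# Frequency (Hz) of DCT-II bin k (0-based) for a length-n signal at rate fs.
dct_freqs <- function(n, fs) (0:(n - 1)) * fs / (2 * n)

# Rotation model. Earth frame is (north, east, up); the earth-to-sensor
# rotation is R(h, p, r) = Rx(roll) %*% Ry(pitch) %*% Rz(heading) with
#   Rz(h) = [[ ch, sh, 0], [-sh, ch, 0], [0, 0, 1]]   (h clockwise from north)
#   Ry(p) = [[ cp, 0, sp], [0, 1, 0], [-sp, 0, cp]]   (p tilts sensor x up)
#   Rx(r) = [[1, 0, 0], [0, cr, sr], [0, -sr, cr]]
# so a sensor at rest reads specific force R %*% c(0, 0, 1) =
# (sin p, sin r cos p, cos r cos p), matching the atan2 extraction formulas.

# Vectorized entries of R(h, p, r); angles in degrees, n-vectors in -> list
# of nine n-vectors r11..r33.
rotmat_entries <- function(heading, pitch, roll) {
  h <- deg2rad(heading); p <- deg2rad(pitch); r <- deg2rad(roll)
  ch <- cos(h); sh <- sin(h)
  cp <- cos(p); sp <- sin(p)
  cr <- cos(r); sr <- sin(r)
  list(
    r11 = cp * ch,                 r12 = cp * sh,                 r13 = sp,
    r21 = -cr * sh - sr * sp * ch, r22 = cr * ch - sr * sp * sh,  r23 = sr * cp,
    r31 = sr * sh - cr * sp * ch,  r32 = -sr * ch - cr * sp * sh, r33 = cr * cp
  )
}

rotmat_hpr <- function(heading, pitch, roll) {
  e <- rotmat_entries(heading, pitch, roll)
  matrix(c(e$r11, e$r21, e$r31, e$r12, e$r22, e$r32, e$r13, e$r23, e$r33),
         nrow = 3)
}

# Rotate one earth-frame vector into the sensor frame along an orientation
# trajectory; returns an n x 3 matrix.
rotate_earth_to_body <- function(heading, pitch, roll, v_earth) {
  e <- rotmat_entries(heading, pitch, roll)
  cbind(
    e$r11 * v_earth[1] + e$r12 * v_earth[2] + e$r13 * v_earth[3],
    e$r21 * v_earth[1] + e$r22 * v_earth[2] + e$r23 * v_earth[3],
    e$r31 * v_earth[1] + e$r32 * v_earth[2] + e$r33 * v_earth[3]
  )
}

# Body-frame angular velocity (deg/s) along an orientation trajectory,
# from the skew part of R[t + 1] %*% t(R[t]); forward difference, the last
# sample repeats so the output aligns with the input grid.
body_rates_from_euler <- function(heading, pitch, roll, fs) {
  e <- rotmat_entries(heading, pitch, roll)
  n <- length(heading)
  if (n < 2L) return(matrix(0, nrow = n, ncol = 3))
  hd <- function(v) v[-1L]    # sample t + 1
  tl <- function(v) v[-n]     # sample t
  a23 <- hd(e$r21) * tl(e$r31) + hd(e$r22) * tl(e$r32) + hd(e$r23) * tl(e$r33)
  a32 <- hd(e$r31) * tl(e$r21) + hd(e$r32) * tl(e$r22) + hd(e$r33) * tl(e$r23)
  a31 <- hd(e$r31) * tl(e$r11) + hd(e$r32) * tl(e$r12) + hd(e$r33) * tl(e$r13)
  a13 <- hd(e$r11) * tl(e$r31) + hd(e$r12) * tl(e$r32) + hd(e$r13) * tl(e$r33)
  a12 <- hd(e$r11) * tl(e$r21) + hd(e$r12) * tl(e$r22) + hd(e$r13) * tl(e$r23)
  a21 <- hd(e$r21) * tl(e$r11) + hd(e$r22) * tl(e$r12) + hd(e$r23) * tl(e$r13)
  w <- cbind((a23 - a32) / 2, (a31 - a13) / 2, (a12 - a21) / 2) * fs
  rad2deg(rbind(w, w[nrow(w), , drop = FALSE]))
}
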