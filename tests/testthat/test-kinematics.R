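# Orientation and body-signal processing: filter response, exact
# static/dynamic additivity, forward-model consistency of the Euler
# angles, circular statistics, normalization invariants.

test_that("the low-pass filter passes DC exactly and slow tones faithfully", {
  fs <- 50
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  # constant in, identical constant out
  expect_equal(lowpass_fir(rep(2.5, length(t)), fs), rep(2.5, length(t)),
               tolerance = 1e-12)
  # slow tone (well below cutoff) preserved in amplitude and phase
  slow <- sin(2 * pi * 0.01 * t)
  y <- lowpass_fir(slow, fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_lt(max(abs(y[mid] - slow[mid])), 0.02)
  # fast tone (well above cutoff) removed
  fast <- sin(2 * pi * 5 * t)
  expect_lt(max(abs(lowpass_fir(fast, fs)[mid])), 1e-3)
  # shape preserved for matrix and data-frame input
  xm <- cbind(a = slow, b = fast)
  ym <- lowpass_fir(xm, fs)
  expect_equal(dim(ym), dim(xm))
  expect_equal(ym[, 1], y, ignore_attr = TRUE)
})

test_that("too-short signals for the filter raise a typed error", {
  expect_error(lowpass_fir(rnorm(100), fs = 100, cutoff = 0.2),
               class = "jellytag_length_error")
})

test_that("static + dynamic reproduces the input to machine precision", {
  set.seed(1)
  fs <- 50
  acc <- matrix(rnorm(3 * 60 * fs), ncol = 3)
  sp <- split_static_dynamic(acc, fs)
  expect_equal(as.matrix(sp$static) + as.matrix(sp$dynamic), acc,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Euler angles invert the gravity/field forward model", {
  set.seed(42)
  field <- c(0.4, 0, -0.35)
  n <- 200
  h <- runif(n, 0, 360); p <- runif(n, -60, 60); r <- runif(n, -170, 170)
  grav <- t(vapply(seq_len(n),
                   function(i) drop(oracle_R(h[i], p[i], r[i]) %*% c(0, 0, 1)),
                   numeric(3)))
  magb <- t(vapply(seq_len(n),
                   function(i) drop(oracle_R(h[i], p[i], r[i]) %*% field),
                   numeric(3)))
  eu <- euler_angles(grav, magb)
  expect_equal(eu$pitch, p, tolerance = 1e-8)
  expect_equal(eu$roll, r, tolerance = 1e-8)
  dh <- wrap180(eu$heading - h)
  expect_lt(max(abs(dh)), 1e-8)
  expect_false(any(eu$degenerate))
})

test_that("Euler angle anchors: level, pitched and rolled postures", {
  # level, x axis pointing north, field pointing north-down
  eu <- euler_angles(matrix(c(0, 0, 1), 1), matrix(c(0.4, 0, -0.35), 1))
  expect_equal(eu$heading, 0)
  expect_equal(eu$pitch, 0)
  expect_equal(eu$roll, 0)
  # pure pitch: gravity moves onto +x as the nose pitches up
  eu <- euler_angles(matrix(c(sin(pi / 6), 0, cos(pi / 6)), 1),
                     matrix(c(0.4, 0, -0.35), 1))
  expect_equal(eu$pitch, 30, tolerance = 1e-10)
  # pure roll
  eu <- euler_angles(matrix(c(0, sin(pi / 4), cos(pi / 4)), 1),
                     matrix(c(0.4, 0, -0.35), 1))
  expect_equal(eu$roll, 45, tolerance = 1e-10)
  # eastward heading: body x east means the field's north component lands
  # on -y in the body frame
  eu <- euler_angles(matrix(c(0, 0, 1), 1), matrix(c(0, -0.4, -0.35), 1))
  expect_equal(eu$heading, 90, tolerance = 1e-10)
})

test_that("gimbal lock and free-fall degeneracy are flagged, not silently used", {
  eu <- euler_angles(matrix(c(sin(deg2rad(80)), 0, cos(deg2rad(80))), 1),
                     matrix(c(0.4, 0, -0.35), 1))
  expect_true(eu$gimbal)
  expect_false(eu$degenerate)
  eu2 <- euler_angles(matrix(c(0.01, 0.01, 0.02), 1),
                      matrix(c(0.4, 0, -0.35), 1))
  expect_true(eu2$degenerate)
  expect_true(is.na(eu2$heading) && is.na(eu2$pitch) && is.na(eu2$roll))
})

test_that("orientation change matches the quaternion oracle and its anchors", {
  expect_equal(orientation_change(c(10, 5, -3), c(10, 5, -3)), 0)
  expect_equal(orientation_change(c(0, 0, 0), c(180, 0, 0)), 180)
  expect_equal(orientation_change(c(350, 0, 0), c(10, 0, 0)), 20,
               tolerance = 1e-10)
  expect_equal(orientation_change(c(0, -10, 0), c(0, 35, 0)), 45,
               tolerance = 1e-10)
  set.seed(7)
  for (i in 1:100) {
    s <- c(runif(1, 0, 360), runif(1, -70, 70), runif(1, -180, 180))
    e <- c(runif(1, 0, 360), runif(1, -70, 70), runif(1, -180, 180))
    got <- orientation_change(s, e)
    want <- oracle_rotation_angle(wrap180(e[1] - s[1]), e[2] - s[2],
                                  wrap180(e[3] - s[3]))
    expect_equal(got, want, tolerance = 1e-8)
    expect_gte(got, 0)
    expect_lte(got, 180)
  }
})

test_that("circular statistics wrap correctly and refuse undefined means", {
  cm <- circular_mean_sd(c(350, 10))
  expect_lt(abs(wrap180(cm$mean - 0)), 1e-10)   # 0 and 360 are the same direction
  cm2 <- circular_mean_sd(c(90, 90, 90))
  expect_equal(cm2$mean, 90)
  expect_equal(cm2$sd, 0, tolerance = 1e-6)
  expect_error(circular_mean_sd(c(0, 90, 180, 270)),
               class = "jellytag_undefined_mean")
  expect_error(circular_mean_sd(NA_real_), class = "jellytag_undefined_mean")
})

test_that("body signals satisfy their normalization and composition identities", {
  set.seed(3)
  dyn <- matrix(rnorm(3000, 0, 0.1), ncol = 3)
  gyr <- matrix(rnorm(3000, 0, 5), ncol = 3)
  sig <- body_signals(dyn, gyr, fs = 100)
  expect_equal(mean(sig$dax_abs_norm), 1, tolerance = 1e-9)
  expect_equal(mean(sig$pdba_norm), 1, tolerance = 1e-9)
  expect_equal(mean(sig$odba_norm), 1, tolerance = 1e-9)
  expect_equal(sig$odba, sig$dax_abs + sig$pdba)
  expect_true(all(sig$dax_abs >= 0 & sig$pdba >= 0 & sig$pav >= 0 &
                  sig$jerk_x_abs >= 0 & sig$jerk_yz_norm >= 0))
  expect_equal(sig$pav, sqrt(gyr[, 2]^2 + gyr[, 3]^2))
  # jerk is the forward difference scaled by fs
  expect_equal(sig$jerk_x_abs[1], abs(dyn[2, 1] - dyn[1, 1]) * 100)
  expect_error(body_signals(matrix(0, 10, 3), gyr[1:10, ], 100),
               class = "jellytag_normalization_error")
})

test_that("noise-free orientation trajectories are recovered below one degree RMS", {
  dep <- quick_deployment(
    seed = 31, duration_s = 420, noise_sd_g = 0, noise_sd_dps = 0,
    noise_sd_mag = 0, tether_fraction = 0, unknown_fraction = 0,
    pulse_freq_hz = 0.4)
  kin <- process_kinematics(dep$record)
  ok <- which(!kin$euler$gimbal & !kin$euler$degenerate)
  edge <- 30 * 100                       # half filter length
  ok <- ok[ok > edge & ok <= nrow(kin$euler) - edge]
  expect_gt(length(ok), 1000)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(wrap180(kin$euler$heading[ok] - dep$truth$euler$heading[ok])), 1)
  expect_lt(rms(kin$euler$pitch[ok] - dep$truth$euler$pitch[ok]), 1)
  expect_lt(rms(wrap180(kin$euler$roll[ok] - dep$truth$euler$roll[ok])), 1)
})
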