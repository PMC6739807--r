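# Featurization: catalog size, sparsity/energy/peak primitives against
# independent oracles, per-period assembly.

test_that("the catalog has 45 uniquely named features, 23 accel + 22 gyro", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 45)
  expect_equal(anyDuplicated(cat$feature), 0)
  expect_equal(sum(cat$sensor == "accel"), 23)
  expect_equal(sum(cat$sensor == "gyro"), 22)
})

test_that("the Gini index matches the mean-difference oracle and its anchors", {
  expect_equal(as.numeric(gini_index(rep(3, 8))), 0, tolerance = 1e-12)
  n <- 10
  expect_equal(as.numeric(gini_index(c(rep(0, n - 1), 5))), 1 - 1 / n,
               tolerance = 1e-12)
  z <- gini_index(rep(0, 5))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(gini_index(c(1, -1)), class = "jellytag_validation_error")
  set.seed(11)
  for (i in 1:100) {
    v <- rexp(sample(3:50, 1))
    expect_equal(as.numeric(gini_index(v)), oracle_gini(v),
                 tolerance = 1e-10)
  }
})

test_that("band energies are additive and concentrate where the tone is", {
  fs <- 100
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t) + 0.2 * sin(2 * pi * 4 * t) + rnorm(length(t), 0, 0.01)
  bands <- c(spectral_energy(x, fs, 1e-9, 0.2), spectral_energy(x, fs, 0.2, 1),
             spectral_energy(x, fs, 1, 8), spectral_energy(x, fs, 8, fs / 2))
  total <- spectral_energy(x, fs, 1e-9, fs / 2)
  expect_equal(sum(bands), total, tolerance = 1e-9)
  # the 0.5 Hz tone dominates the pulse band, the 4 Hz tone the mid band
  expect_gt(bands[2], 10 * bands[4])
  expect_gt(bands[2], bands[3])
  expect_gt(bands[3], 20 * bands[4])
  # an empty band on a very short series is flagged, not an error
  e <- spectral_energy(sin(1:4), fs = 100, f_lo = 0.2, f_hi = 1)
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "empty_band"))
})

test_that("peak counting matches the exhaustive oracle on continuous signals", {
  fs <- 50
  set.seed(21)
  for (i in 1:100) {
    n <- sample(60:300, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
    x[is.na(x)] <- 0
    h <- quantile(abs(x), 0.5)
    sep <- runif(1, 0.05, 0.5)
    expect_equal(count_peaks(x, h, sep, fs),
                 oracle_count_peaks(x, h, sep * fs))
  }
  # a clean tone has one peak per cycle
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 0.5 * t)
  expect_equal(count_peaks(tone, 0.5, 0.5, fs), 5L)
  # plateaus count once
  expect_equal(count_peaks(c(0, 1, 1, 1, 0, 0, 2, 0), 0.5, 0.04, fs), 2L)
  # ... and merge with a taller neighbor when closer than the separation
  expect_equal(count_peaks(c(0, 1, 1, 1, 0, 0, 2, 0), 0.5, 1, fs), 1L)
})

test_that("featurized periods carry the full catalog plus ODBA and orientation columns", {
  dep <- quick_deployment(seed = 23, duration_s = 120)
  proc <- process_deployment(dep$record, dep$annotations,
                             source = "laboratory")
  f <- proc$features
  expect_true(all(feature_catalog()$feature %in% names(f)))
  expect_true(all(c("odba_norm_mean", "odba_norm_max", "orientation_change",
                    "gimbal_excluded") %in% names(f)))
  num <- as.matrix(f[, feature_catalog()$feature])
  expect_true(all(is.finite(num)))
  expect_true(all(f$odba_norm_max >= f$odba_norm_mean))
  oc <- f$orientation_change[!f$gimbal_excluded]
  expect_true(all(oc >= 0 & oc <= 180))
  expect_equal(nrow(f), nrow(proc$periods))
  # period statistics are literal summaries of the body-signal slice
  i <- which(f$eligible)[1]
  sl <- proc$kin$signals[f$start_sample[i]:f$end_sample[i], ]
  expect_equal(f$dax_norm_max[i], max(sl$dax_abs_norm))
  expect_equal(f$pdba_norm_mean[i], mean(sl$pdba_norm))
  expect_equal(f$jerk_x_sd[i], sd(sl$jerk_x_abs))
  expect_equal(f$odba_norm_mean[i], mean(sl$odba_norm))
  expect_equal(f$da_yz_corr[i], cor(sl$da_y, sl$da_z))
  expect_equal(f$avx_mean[i], mean(sl$avx_abs))
  expect_equal(
    f$dax_spec_gini[i],
    as.numeric(gini_index(Mod(fft(sl$dax_abs_norm))[
      seq_len(ceiling(nrow(sl) / 2))])))
})

test_that("feature tables round-trip through CSV", {
  dep <- quick_deployment(seed = 23, duration_s = 60)
  proc <- process_deployment(dep$record, dep$annotations, source = "in_situ")
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(proc$features, p)
  back <- read_feature_table(p)
  expect_equal(nrow(back), nrow(proc$features))
  expect_equal(back$dax_norm_max, proc$features$dax_norm_max,
               tolerance = 1e-12)
})

test_that("swimming periods are separable from drifting in normalized ODBA", {
  dep <- quick_deployment(seed = 29, duration_s = 400, drift_fraction = 0.2,
                          tether_fraction = 0)
  proc <- process_deployment(dep$record, dep$annotations, source = "in_situ")
  f <- dplyr::filter(proc$features, .data$eligible)
  expect_true(all(c("swim", "drift") %in% f$activity))
  expect_gt(min(f$odba_norm_mean[f$activity == "swim"]),
            max(f$odba_norm_mean[f$activity == "drift"]))
})
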