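# Synthetic deployment generator: determinism, validation, statistical
# calibration of the behavioral states, amplitude ordering of the regimes.

test_that("the generator is deterministic given the config seed", {
  d1 <- quick_deployment(seed = 3, duration_s = 30)
  d2 <- quick_deployment(seed = 3, duration_s = 30)
  expect_identical(d1$record$motion, d2$record$motion)
  expect_identical(d1$truth$labels, d2$truth$labels)
  expect_identical(as.data.frame(d1$annotations), as.data.frame(d2$annotations))

  d3 <- quick_deployment(seed = 4, duration_s = 30)
  expect_false(isTRUE(all.equal(d1$record$motion$ax, d3$record$motion$ax)))
})

test_that("sim_config rejects invalid settings", {
  expect_error(sim_config(drift_fraction = -0.1),
               class = "jellytag_validation_error")
  expect_error(sim_config(drift_fraction = 0.6, tether_fraction = 0.5),
               class = "jellytag_validation_error")
  expect_error(sim_config(pulse_freq_hz = 60),
               class = "jellytag_validation_error")
  expect_error(sim_config(duration_s = 10.5),
               class = "jellytag_validation_error")
  expect_error(sim_config(mag_field_vector = c(0, 0, -1)),
               class = "jellytag_validation_error")
  expect_error(sim_config(tether_amp_g = 0.5),
               class = "jellytag_validation_error")
})

test_that("renewal bouts hit the target time fractions on average", {
  fracs <- vapply(1:30, function(s) {
    set.seed(s)
    mean(jellytag:::renewal_states(1800L, 0.08, 8))
  }, numeric(1))
  expect_gt(mean(fracs), 0.08 - 0.02)
  expect_lt(mean(fracs), 0.08 + 0.02)

  set.seed(1)
  expect_equal(jellytag:::renewal_states(100L, 0, 10), rep(FALSE, 100))
  expect_equal(jellytag:::renewal_states(100L, 1, 10), rep(TRUE, 100))
})

test_that("truth labels, annotations and unknown masking are consistent", {
  dep <- quick_deployment(seed = 11, duration_s = 400,
                          unknown_fraction = 0.2)
  lab <- dep$truth$labels
  expect_equal(nrow(lab), 400)
  expect_true(all(lab$activity %in% c("swim", "drift")))
  expect_true(all(lab$tether %in% c("taut", "slack")))

  # rasterize the annotations back to seconds; every non-unknown second
  # must agree with the ground truth
  sec_act <- rep("unknown", 400)
  sec_tet <- rep("unknown", 400)
  for (i in seq_len(nrow(dep$annotations))) {
    idx <- (dep$annotations$start_s[i] + 1):dep$annotations$end_s[i]
    sec_act[idx] <- dep$annotations$activity[i]
    sec_tet[idx] <- dep$annotations$tether[i]
  }
  known <- sec_act != "unknown"
  expect_equal(sec_act[known], lab$activity[known])
  expect_equal(sec_tet[known], lab$tether[known])
  # unknown seconds mask both labels together, at roughly the target rate
  expect_equal(sec_act == "unknown", sec_tet == "unknown")
  expect_gt(mean(!known), 0.08)
  expect_lt(mean(!known), 0.35)
})

test_that("regime amplitudes order as tether-influenced > swimming > drifting", {
  dep <- quick_deployment(seed = 13, duration_s = 600,
                          drift_fraction = 0.15, tether_fraction = 0.15)
  lab <- dep$truth$labels
  # per-second within-second s.d. of raw ax as a model-free activity proxy
  ax <- dep$record$motion$ax
  per_sec <- vapply(seq_len(nrow(lab)), function(s) {
    sd(ax[((s - 1) * 100 + 1):(s * 100)])
  }, numeric(1))
  infl <- lab$tether == "taut"
  swim <- !infl & lab$activity == "swim"
  drift <- !infl & lab$activity == "drift"
  expect_true(all(c(sum(infl), sum(swim), sum(drift)) > 3))
  expect_gt(mean(per_sec[infl]), mean(per_sec[swim]))
  expect_gt(mean(per_sec[swim]), mean(per_sec[drift]))
  # drifting seconds carry essentially only sensor noise
  expect_lt(mean(per_sec[drift]), 3 * dep$config$noise_sd_g)
})

test_that("accelerometer norm at rest reflects gravity and the magnetometer the field", {
  dep <- quick_deployment(seed = 17, duration_s = 120, noise_sd_g = 0,
                          noise_sd_dps = 0, noise_sd_mag = 0,
                          drift_fraction = 1, tether_fraction = 0)
  m <- dep$record$motion
  expect_equal(mean(sqrt(m$ax^2 + m$ay^2 + m$az^2)), 1, tolerance = 1e-6)
  f <- sqrt(sum(sim_config()$mag_field_vector^2))
  expect_equal(mean(sqrt(m$mx^2 + m$my^2 + m$mz^2)), f, tolerance = 1e-6)
})

test_that("Gaussian feature sampler matches its parameters and validates input", {
  mu0 <- c(0, 0); mu1 <- c(2, -1)
  s0 <- diag(2); s1 <- matrix(c(2, 0.5, 0.5, 1), 2)
  d <- simulate_gaussian_features(mu0, mu1, s0, s1, alpha = 0.3,
                                  n = 40000, seed = 9)
  expect_named(d, c("f1", "f2", "label"))
  expect_equal(mean(d$label), 0.3, tolerance = 0.02)
  x1 <- as.matrix(d[d$label == 1, c("f1", "f2")])
  expect_equal(colMeans(x1), mu1, tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(unname(cov(x1)), s1, tolerance = 0.1)

  d2 <- simulate_gaussian_features(mu0, mu1, s0, s1, 0.3, 100, seed = 9)
  d3 <- simulate_gaussian_features(mu0, mu1, s0, s1, 0.3, 100, seed = 9)
  expect_identical(d2, d3)

  bad <- matrix(c(1, 2, 2, 1), 2)   # not positive definite
  expect_error(simulate_gaussian_features(mu0, mu1, bad, s1, 0.3, 10),
               class = "jellytag_validation_error")
})
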