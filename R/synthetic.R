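# Synthetic tag-deployment generator. Emulates the statistical structure the
# analysis assumes -- pulsed bell-contraction acceleration at 0.25-0.50 Hz,
# rare low-amplitude drifting bouts, high-amplitude tether-yank transients
# with an orientation step, a slowly varying orientation observed through a
# gravity/geomagnetic forward model, and additive sensor noise -- so that
# every downstream stage can be exercised against known ground truth.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: a pulse
#' frequency drawn uniformly from 0.25-0.50 Hz (the typical range for
#' swimming medusae), drifting occupying a few percent of time in bouts of
#' tens of seconds (observed range 0.5-4.3%), occasional tether-influenced
#' bouts with transients several times the swim amplitude, and a heading
#' random walk with a pitch mean-reverting around +20 deg.
#'
#' @param duration_s record duration in seconds (integer).
#' @param pulse_freq_hz bell pulse frequency in Hz; `NULL` draws one
#'   uniformly from `[0.25, 0.50]`.
#' @param swim_amp_g peak dynamic acceleration of the propulsive (x) thrust
#'   in g.
#' @param drift_fraction target fraction of time drifting.
#' @param drift_bout_s mean drifting bout length (s, exponential).
#' @param tether_fraction target fraction of time tether-influenced.
#' @param tether_bout_s mean influenced bout length (s, exponential).
#' @param tether_amp_g transient amplitude as a multiple (>1) of
#'   `swim_amp_g`.
#' @param unknown_fraction fraction of annotated seconds marked unknown
#'   (uniformly at random); ground truth keeps the real labels.
#' @param heading_walk_deg_per_sqrt_s heading random-walk scale.
#' @param pitch_mean_deg,pitch_sd_deg,pitch_tau_s Ornstein-Uhlenbeck pitch
#'   process: mean, stationary s.d., relaxation time.
#' @param roll_amp_deg,roll_period_s slow sinusoidal roll.
#' @param swim_av_dps pulse-locked gyroscope oscillation amplitude while
#'   swimming (deg/s).
#' @param noise_sd_g,noise_sd_dps,noise_sd_mag per-sample Gaussian sensor
#'   noise s.d. for accelerometer (g), gyroscope (deg/s), magnetometer.
#' @param mag_field_vector geomagnetic field in the earth frame
#'   (north, east, up), arbitrary consistent units; must have a nonzero
#'   horizontal component.
#' @param depth_mean_m,depth_amp_m,depth_period_s slow sinusoidal depth
#'   profile (pressure in dbar is numerically equal to depth in m).
#' @param fs_motion,fs_slow sampling rates (Hz).
#' @param seed integer random seed driving every stream of the generator.
#' @return a validated list of class `jellytag_sim_config`.
#' @export
sim_config <- function(duration_s = 1800,
                       pulse_freq_hz = NULL,
                       swim_amp_g = 0.2,
                       drift_fraction = 0.03,
                       drift_bout_s = 20,
                       tether_fraction = 0.08,
                       tether_bout_s = 8,
                       tether_amp_g = 3,
                       unknown_fraction = 0.05,
                       heading_walk_deg_per_sqrt_s = 1,
                       pitch_mean_deg = 20, pitch_sd_deg = 15,
                       pitch_tau_s = 300,
                       roll_amp_deg = 15, roll_period_s = 300,
                       swim_av_dps = 15,
                       noise_sd_g = 0.02, noise_sd_dps = 1,
                       noise_sd_mag = 0.005,
                       mag_field_vector = c(0.4, 0, -0.35),
                       depth_mean_m = 10, depth_amp_m = 5,
                       depth_period_s = 600,
                       fs_motion = 100, fs_slow = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  if (!frac_ok(drift_fraction) || !frac_ok(tether_fraction) ||
      !frac_ok(unknown_fraction) ||
      drift_fraction + tether_fraction > 1) {
    abort_jt("fractions must lie in [0, 1] with drift + tether <= 1",
             "validation_error")
  }
  if (!is.null(pulse_freq_hz) &&
      (pulse_freq_hz <= 0 || pulse_freq_hz >= fs_motion / 2)) {
    abort_jt("pulse_freq_hz must lie in (0, fs_motion / 2)",
             "validation_error")
  }
  if (duration_s < 1 || duration_s != round(duration_s)) {
    abort_jt("duration_s must be a positive whole number of seconds",
             "validation_error")
  }
  if (sqrt(sum(mag_field_vector[1:2]^2)) <= 0) {
    abort_jt("mag_field_vector needs a nonzero horizontal component",
             "validation_error")
  }
  if (tether_amp_g <= 1) {
    abort_jt("tether_amp_g must exceed 1 (a multiple of swim_amp_g)",
             "validation_error")
  }
  structure(cfg, class = "jellytag_sim_config")
}

# Alternating renewal process rasterized to whole seconds: state 2 ("on")
# bouts are exponential with mean on_mean; the "off" mean is set so the
# long-run on fraction matches `fraction`.
renewal_states <- function(n_s, fraction, on_mean) {
  if (fraction <= 0) return(rep(FALSE, n_s))
  if (fraction >= 1) return(rep(TRUE, n_s))
  off_mean <- on_mean * (1 - fraction) / fraction
  state <- runif(1) < fraction
  out <- logical(0)
  while (length(out) < n_s) {
    len <- max(1L, as.integer(ceiling(rexp(1, 1 / if (state) on_mean else off_mean))))
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n_s)]
}

#' Generate a synthetic deployment with ground truth
#'
#' Builds one tag deployment under the forward model: the orientation
#' trajectory (heading random walk, mean-reverting pitch, slow sinusoidal
#' roll, plus a heading step at each tether-bout onset) is observed through
#' the gravity and geomagnetic forward model; swimming epochs superimpose a
#' periodic propulsive thrust on the x axis (per-cycle half-sine burst with
#' duty cycle 0.4 plus a 25% second harmonic in quadrature, zero-mean over
#' each cycle)
#' with smaller random-phase y/z components and a pulse-locked gyroscope
#' oscillation; drifting epochs contain only sensor noise; tether-influenced
#' bouts superimpose an exponentially decaying yank transient and a
#' sustained 2.5 Hz drag oscillation of amplitude
#' `tether_amp_g * swim_amp_g` on both accelerometer and gyroscope.
#' The annotation track labels each second truthfully except for a random
#' `unknown_fraction` of seconds marked unknown.
#'
#' The generator is deterministic: the same `config` (including `seed`)
#' reproduces the output bit for bit.
#'
#' @param config a [sim_config()].
#' @return a list of class `jellytag_deployment` with elements `record`
#'   (a [tag_record()]), `annotations` (an [annotation_track()]) and
#'   `truth` (list: per-second `labels` tibble, per-sample `euler` tibble,
#'   `pulse_freq_hz`).
#' @export
simulate_deployment <- function(config = sim_config()) {
  stopifnot(inherits(config, "jellytag_sim_config"))
  c_ <- config
  set.seed(c_$seed)
  fs <- c_$fs_motion
  n_s <- as.integer(c_$duration_s)
  n <- n_s * fs
  t <- (0:(n - 1)) / fs

  pulse <- c_$pulse_freq_hz %||% runif(1, 0.25, 0.50)

  # per-second behavioral states
  drifting <- renewal_states(n_s, c_$drift_fraction, c_$drift_bout_s)
  influenced <- renewal_states(n_s, c_$tether_fraction, c_$tether_bout_s)
  sec_of <- pmin(floor(t) + 1L, n_s)            # sample -> second index
  swim_mask <- !drifting[sec_of]
  infl_mask <- influenced[sec_of]

  # orientation trajectory
  dt <- 1 / fs
  heading <- cumsum(rnorm(n, 0, c_$heading_walk_deg_per_sqrt_s * sqrt(dt))) +
    runif(1, 0, 360)
  onsets <- which(influenced & !c(FALSE, influenced[-n_s]))   # bout starts
  if (length(onsets)) {
    steps <- sample(c(-1, 1), length(onsets), replace = TRUE) *
      runif(length(onsets), 40, 120)
    step_sig <- numeric(n)
    step_sig[(onsets - 1L) * fs + 1L] <- steps
    heading <- heading + cumsum(step_sig)
  }
  phi <- exp(-dt / c_$pitch_tau_s)
  innov <- rnorm(n, 0, c_$pitch_sd_deg * sqrt(1 - phi^2))
  pitch <- c_$pitch_mean_deg +
    as.numeric(stats::filter(innov, phi, method = "recursive",
                             init = rnorm(1, 0, c_$pitch_sd_deg)))
  pitch <- pmin(89, pmax(-89, pitch))
  roll <- c_$roll_amp_deg * sin(2 * pi * t / c_$roll_period_s + runif(1, 0, 2 * pi))

  # propulsive thrust: zero-mean-per-cycle burst waveform on x
  u <- (pulse * t) %% 1
  # the 25% second harmonic is added in quadrature to the burst's intrinsic
  # second harmonic so the waveform's dominant spectral line stays at the
  # pulse fundamental (in-phase addition would push the second harmonic
  # slightly above the fundamental and make the RPF argmax bistable)
  burst <- ifelse(u < 0.4, sin(pi * u / 0.4), 0) - 0.4 * 2 / pi
  wave_x <- burst + 0.25 * cos(4 * pi * u)
  ph_y <- runif(1, 0, 2 * pi); ph_z <- runif(1, 0, 2 * pi)
  dyn <- cbind(
    c_$swim_amp_g * wave_x * swim_mask,
    0.3 * c_$swim_amp_g * sin(2 * pi * pulse * t + ph_y) * swim_mask,
    0.3 * c_$swim_amp_g * sin(2 * pi * pulse * t + ph_z) * swim_mask
  )

  # tether influence: yank transient at bout onset + sustained drag
  tamp <- c_$tether_amp_g * c_$swim_amp_g
  if (length(onsets)) {
    yank <- numeric(n)
    for (s0 in onsets) {
      i0 <- (s0 - 1L) * fs + 1L
      idx <- i0:min(n, i0 + 2L * fs)
      tt <- (idx - i0) / fs
      yank[idx] <- yank[idx] + exp(-tt / 0.4) * sin(2 * pi * 3.5 * tt)
    }
    w <- runif(3, 0.5, 1)
    dyn <- dyn + tamp * yank %o% w
  }
  drag <- 0.6 * tamp * sin(2 * pi * 2.5 * t + runif(1, 0, 2 * pi)) * infl_mask
  dyn <- dyn + cbind(drag, 0.7 * drag, 0.7 * drag)

  # sensor channels through the forward model
  grav <- rotate_earth_to_body(heading, pitch, roll, c(0, 0, 1))
  magb <- rotate_earth_to_body(heading, pitch, roll, c_$mag_field_vector)
  omega <- body_rates_from_euler(heading, pitch, roll, fs)
  gyro_pulse <- cbind(
    (c_$swim_av_dps / 3) * sin(2 * pi * pulse * t + ph_z),
    c_$swim_av_dps * sin(2 * pi * pulse * t + ph_y),
    c_$swim_av_dps * sin(2 * pi * pulse * t + ph_y + pi / 2)
  ) * swim_mask
  gyro_drag <- cbind(0.5, 1, 1)[rep(1, n), ] *
    (2.5 * c_$swim_av_dps) * sin(2 * pi * 2.5 * t) * infl_mask

  accel <- grav + dyn + matrix(rnorm(3 * n, 0, c_$noise_sd_g), ncol = 3)
  gyro <- omega + gyro_pulse + gyro_drag +
    matrix(rnorm(3 * n, 0, c_$noise_sd_dps), ncol = 3)
  mag <- magb + matrix(rnorm(3 * n, 0, c_$noise_sd_mag), ncol = 3)

  motion <- tibble(
    time = t,
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    mx = mag[, 1], my = mag[, 2], mz = mag[, 3]
  )
  t_s <- 0:(n_s - 1)
  slow <- tibble(
    time = as.numeric(t_s),
    pressure = c_$depth_mean_m +
      c_$depth_amp_m * sin(2 * pi * t_s / c_$depth_period_s),
    temperature = 12 + rnorm(n_s, 0, 0.01),
    light = 100 + rnorm(n_s, 0, 1)
  )
  record <- tag_record(motion, slow, deployment_id = sprintf("sim-%d", c_$seed),
                       fs_motion = fs, fs_slow = c_$fs_slow)

  truth_labels <- tibble(
    second = t_s,
    activity = ifelse(drifting, "drift", "swim"),
    tether = ifelse(influenced, "taut", "slack")
  )
  unknown <- runif(n_s) < c_$unknown_fraction
  ann <- truth_labels
  ann$activity[unknown] <- "unknown"
  ann$tether[unknown] <- "unknown"
  annotations <- annotation_track(
    seconds_to_intervals(ann), deployment_id = record$deployment_id)

  truth <- list(
    labels = truth_labels,
    euler = tibble(time = t, heading = wrap360(heading), pitch = pitch,
                   roll = wrap180(roll)),
    pulse_freq_hz = pulse
  )
  structure(list(record = record, annotations = annotations, truth = truth,
                 config = config),
            class = "jellytag_deployment")
}

# Compress a per-second label tibble (second, activity, tether) into
# half-open intervals of constant labels.
seconds_to_intervals <- function(sec_labels) {
  key <- paste(sec_labels$activity, sec_labels$tether)
  run <- c(0L, cumsum(key[-1L] != key[-length(key)]))
  sec_labels |>
    mutate(.run = run) |>
    group_by(.data$.run) |>
    summarise(start_s = min(.data$second),
              end_s = max(.data$second) + 1,
              activity = .data$activity[1],
              tether = .data$tether[1],
              .groups = "drop") |>
    select("start_s", "end_s", "activity", "tether")
}

#' @export
print.jellytag_deployment <- function(x, ...) {
  lab <- x$truth$labels
  cat(sprintf(
    "<jellytag_deployment> %s: %d s, pulse %.3f Hz, drift %.1f%%, influenced %.1f%%\n",
    x$record$deployment_id, nrow(lab), x$truth$pulse_freq_hz,
    100 * mean(lab$activity == "drift"), 100 * mean(lab$tether == "taut")))
  invisible(x)
}

#' Sample labeled features from a two-class Gaussian mixture
#'
#' Direct sampler of the generative model behind quadratic discriminant
#' analysis: `y ~ Bernoulli(alpha)`, `x | y = c ~ N(mu_c, sigma_c)`. Used to
#' validate the fitting, posterior and evaluation machinery against known
#' parameters.
#'
#' @param mu0,mu1 class mean vectors (length p).
#' @param sigma0,sigma1 class covariance matrices (p x p, symmetric positive
#'   definite).
#' @param alpha class-1 prior in (0, 1).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return a tibble with feature columns `f1 ... fp` and an integer `label`
#'   column.
#' @export
simulate_gaussian_features <- function(mu0, mu1, sigma0, sigma1, alpha, n,
                                       seed = NULL) {
  p <- length(mu0)
  stopifnot(length(mu1) == p, all(dim(sigma0) == p), all(dim(sigma1) == p),
            alpha > 0, alpha < 1, n >= 1)
  chol0 <- tryCatch(chol(sigma0), error = function(e) NULL)
  chol1 <- tryCatch(chol(sigma1), error = function(e) NULL)
  if (is.null(chol0) || is.null(chol1) ||
      !isTRUE(all.equal(sigma0, t(sigma0))) ||
      !isTRUE(all.equal(sigma1, t(sigma1)))) {
    abort_jt("covariance matrices must be symmetric positive definite",
             "validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  y <- rbinom(n, 1L, alpha)
  z <- matrix(rnorm(n * p), nrow = n)
  x <- matrix(NA_real_, nrow = n, ncol = p)
  if (any(y == 0L)) {
    x[y == 0L, ] <- z[y == 0L, , drop = FALSE] %*% chol0 +
      matrix(mu0, sum(y == 0L), p, byrow = TRUE)
  }
  if (any(y == 1L)) {
    x[y == 1L, ] <- z[y == 1L, , drop = FALSE] %*% chol1 +
      matrix(mu1, sum(y == 1L), p, byrow = TRUE)
  }
  colnames(x) <- paste0("f", seq_len(p))
  out <- as_tibble(as.data.frame(x))
  out$label <- as.integer(y)
  out
}
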