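# Independent reference implementations used as oracles. These deliberately
# take different computational routes from the package code.

# Gini via the classical mean-absolute-difference identity.
oracle_gini <- function(v) {
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / (2 * n^2 * mean(v))
}

# Precision/recall by explicit confusion matrices at every unique score.
oracle_pr <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(ths, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    data.frame(threshold = th, precision = tp / (tp + fp),
               recall = tp / (tp + fn))
  }))
}

# Step-wise average precision from the oracle sweep.
oracle_auprc <- function(scores, labels) {
  pr <- oracle_pr(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

# Gaussian class-1 posterior via direct density ratio (solve/det route).
oracle_posterior <- function(model, x) {
  dens <- function(x, mu, sigma) {
    p <- length(mu)
    d <- x - mu
    exp(-0.5 * drop(t(d) %*% solve(sigma, d))) /
      sqrt((2 * pi)^p * det(sigma))
  }
  a <- model$alpha * dens(x, model$mu1, model$sigma1)
  b <- (1 - model$alpha) * dens(x, model$mu0, model$sigma0)
  a / (a + b)
}

# Earth-to-sensor matrix built as an explicit product of the three
# elementary frame rotations (heading about z, then pitch about y, then
# roll about x), written out matrix-by-matrix rather than as expanded
# entry formulas.
oracle_R <- function(h, p, r) {
  d <- pi / 180
  Rz <- matrix(c(cos(h * d), sin(h * d), 0,
                 -sin(h * d), cos(h * d), 0,
                 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(p * d), 0, sin(p * d),
                 0, 1, 0,
                 -sin(p * d), 0, cos(p * d)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0,
                 0, cos(r * d), sin(r * d),
                 0, -sin(r * d), cos(r * d)), 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

# Quaternion helpers: q = (w, x, y, z), unit axis quaternions composed
# in the same order as oracle_R.
quat_axis <- function(axis, angle_deg) {
  a <- angle_deg * pi / 360
  q <- c(cos(a), sin(a) * axis)
  q
}
quat_mult <- function(q1, q2) {
  w1 <- q1[1]; v1 <- q1[2:4]
  w2 <- q2[1]; v2 <- q2[2:4]
  c(w1 * w2 - sum(v1 * v2),
    w1 * v2 + w2 * v1 + c(v1[2] * v2[3] - v1[3] * v2[2],
                          v1[3] * v2[1] - v1[1] * v2[3],
                          v1[1] * v2[2] - v1[2] * v2[1]))
}
oracle_rotation_angle <- function(dh, dp, dr) {
  # the package composition Rx'(dr) Ry'(dp) Rz'(dh) corresponds to active
  # rotations by (-dr) about x, (+dp) about y, (-dh) about z, in that order
  q <- quat_mult(quat_axis(c(1, 0, 0), -dr),
                 quat_mult(quat_axis(c(0, 1, 0), dp),
                           quat_axis(c(0, 0, 1), -dh)))
  2 * acos(min(1, abs(q[1]))) * 180 / pi
}

# Exhaustive strict-local-maximum scan with greedy-by-height separation
# pruning. Only valid for signals without exact ties/plateaus; tests feed it
# continuous-valued noise.
oracle_count_peaks <- function(x, min_height, min_sep_samples) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i - 1] < x[i] && x[i + 1] < x[i] && x[i] >= min_height) {
      cand <- c(cand, i)
    }
  }
  cand <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_sep_samples)) {
      kept <- c(kept, i)
    }
  }
  length(kept)
}

# Small synthetic deployment shared across tests.
quick_deployment <- function(seed = 42, duration_s = 300, ...) {
  simulate_deployment(sim_config(duration_s = duration_s, seed = seed, ...))
}

# Minimal valid motion/slow tibbles for io tests.
tiny_motion <- function(n = 5, fs = 100) {
  tibble::tibble(
    time = (0:(n - 1)) / fs,
    ax = 0, ay = 0, az = 1, gx = 0, gy = 0, gz = 0,
    mx = 0.4, my = 0, mz = -0.3
  )
}
tiny_slow <- function(n = 1) {
  tibble::tibble(time = 0:(n - 1), pressure = 10, temperature = 12,
                 light = 100)
}
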