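# End-to-end orchestration: training-data policy, tether and activity
# classifier training, prediction on unannotated deployments, activity
# budgets and orientation summaries, baselines, and the rank-based group
# comparisons.

#' Training-data policy
#'
#' Encodes which periods are eligible to train each task and which category
#' is "class 1" (the positive class for precision/recall). The tether task
#' trains on in-situ periods only (laboratory tether influence is a
#' different phenomenon: gentle turning at the tether end rather than
#' yanking or dragging); the activity task trains on the union of
#' laboratory and in-situ tether-uninfluenced periods (or laboratory only
#' for the domain-transfer variant). Class 1 defaults follow the study
#' convention -- `uninfluenced` for the tether task and `drifting` for the
#' activity task; [train_task()] warns when the configured class 1 is not
#' the empirical minority.
#'
#' @param activity_lab_only restrict activity training to laboratory
#'   periods.
#' @param tether_class1,activity_class1 positive-class names.
#' @return a list of class `jellytag_policy`.
#' @export
training_policy <- function(activity_lab_only = FALSE,
                            tether_class1 = "uninfluenced",
                            activity_class1 = "drifting") {
  stopifnot(tether_class1 %in% c("influenced", "uninfluenced"),
            activity_class1 %in% c("swimming", "drifting"))
  structure(list(activity_lab_only = activity_lab_only,
                 tether_class1 = tether_class1,
                 activity_class1 = activity_class1),
            class = "jellytag_policy")
}

# Map task labels: activity column holds swim/drift; positive-class names
# use the behavioral nouns.
activity_label <- function(x) c(swim = "swimming", drift = "drifting")[x]

#' Select training rows for a task
#'
#' @param features featurized period table (see [featurize_periods()]),
#'   possibly row-bound across deployments.
#' @param task `"tether"` or `"activity"`.
#' @param policy a [training_policy()].
#' @return the eligible rows with a `label` column (class-1 indicator
#'   0/1).
#' @export
eligible_training_rows <- function(features, task = c("tether", "activity"),
                                   policy = training_policy()) {
  task <- match.arg(task)
  f <- as_tibble(features)
  if (task == "tether") {
    f <- filter(f, .data$source == "in_situ", .data$eligible,
                .data$tether != "unknown")
    f$label <- as.integer(f$tether == policy$tether_class1)
  } else {
    f <- filter(f, .data$eligible, .data$tether == "uninfluenced",
                .data$activity != "unknown")
    if (policy$activity_lab_only) f <- filter(f, .data$source == "laboratory")
    f$label <- as.integer(activity_label(f$activity) == policy$activity_class1)
  }
  f
}

#' Train a classification task
#'
#' Applies the training policy, runs the bias-free nested cross-validated
#' evaluation, then trains the final deployable classifier on all eligible
#' data: sequential forward selection (inner CV) chooses the features, QDA
#' is fitted on the full eligible set, and the decision threshold is the
#' equal-error-rate threshold from the cross-validation's averaged
#' precision-recall curve.
#'
#' @inheritParams eligible_training_rows
#' @param seed integer seed fixing folds and selection.
#' @param candidates candidate feature names (default: the full 45-feature
#'   catalog; pass the accelerometer subset for the accelerometry-only
#'   variant).
#' @param k_outer,k_inner,min_delta,ridge see [nested_cv()].
#' @return a list of class `jellytag_task_fit` with elements `model` (a
#'   [fit_qda()] classifier carrying the selected features and EER
#'   threshold), `report` (a [nested_cv()] report), `task` and `n`.
#' @export
train_task <- function(features, task = c("tether", "activity"),
                       policy = training_policy(), seed = 1L,
                       candidates = NULL, k_outer = 5, k_inner = 5,
                       min_delta = 0.02, ridge = 1e-6) {
  task <- match.arg(task)
  rows <- eligible_training_rows(features, task, policy)
  if (nrow(rows) == 0L || length(unique(rows$label)) < 2L) {
    abort_jt(sprintf("policy-filtered %s training set lacks a class", task),
             "training_error")
  }
  class1 <- if (task == "tether") policy$tether_class1 else policy$activity_class1
  if (mean(rows$label) > 0.5) {
    warn(sprintf(
      "configured class 1 '%s' is not the empirical minority (%.1f%% of training periods)",
      class1, 100 * mean(rows$label)))
  }
  candidates <- candidates %||% feature_catalog()$feature
  x <- rows[, candidates, drop = FALSE]
  y <- rows$label
  report <- nested_cv(x, y, candidates = candidates, k_outer = k_outer,
                      k_inner = k_inner, min_delta = min_delta, seed = seed,
                      ridge = ridge)
  sel <- sfs(x, y, candidates = candidates, k_inner = k_inner,
             min_delta = min_delta, seed = seed, ridge = ridge)
  sel <- as.character(sel)
  if (!length(sel)) {
    sel <- attr(sfs(x, y, candidates = candidates, k_inner = k_inner,
                    min_delta = 0, seed = seed, ridge = ridge),
                "trace")$feature[1]
  }
  model <- suppressWarnings(fit_qda(
    rows[, sel, drop = FALSE], y, ridge = ridge,
    threshold = report$eer_threshold, class1_name = class1))
  structure(list(model = model, report = report, task = task,
                 policy = policy, n = nrow(rows), seed = seed),
            class = "jellytag_task_fit")
}

#' @export
print.jellytag_task_fit <- function(x, ...) {
  cat(sprintf("<jellytag_task_fit> task '%s', n = %d periods\n", x$task, x$n))
  print(x$model)
  print(x$report)
  invisible(x)
}

#' Predict behavior on a deployment
#'
#' Segments the whole record into pulse periods, classifies each period's
#' tether influence, removes influenced periods, classifies the remaining
#' uninfluenced periods as swimming or drifting, and summarizes the
#' deployment: fraction of periods tether-influenced, fraction drifting
#' among uninfluenced, per-period orientation change, circular mean and
#' s.d. of heading and roll (gimbal-excluded periods omitted), and
#' normalized-ODBA summaries.
#'
#' @param record a [tag_record()].
#' @param tether_fit,activity_fit `jellytag_task_fit` objects (or bare
#'   `jellytag_qda` models) trained on this feature catalog.
#' @param ... passed to [process_deployment()] (e.g. `search_band`,
#'   `cutoff`).
#' @return a list of class `jellytag_prediction` with `periods` (labeled
#'   period table with posteriors) and `summary` (one-row tibble).
#' @export
predict_deployment <- function(record, tether_fit, activity_fit, ...) {
  tether_model <- as_qda(tether_fit)
  activity_model <- as_qda(activity_fit)
  proc <- process_deployment(record, annotations = NULL, ...)
  feats <- proc$features
  if (nrow(feats) == 0L) {
    abort_jt("record yielded no periods", "validation_error")
  }
  post_t <- qda_posterior(tether_model, feats)
  is1_t <- post_t >= tether_model$threshold
  # posterior is for the configured class 1; express as influenced/uninfluenced
  if (tether_model$class1_name == "uninfluenced") {
    tether_label <- ifelse(is1_t, "uninfluenced", "influenced")
  } else {
    tether_label <- ifelse(is1_t, "influenced", "uninfluenced")
  }
  feats$tether_label <- tether_label
  feats$tether_posterior <- post_t
  feats$activity_label <- NA_character_
  feats$activity_posterior <- NA_real_
  un <- which(tether_label == "uninfluenced")
  if (length(un)) {
    post_a <- qda_posterior(activity_model, feats[un, ])
    is1_a <- post_a >= activity_model$threshold
    pos <- activity_model$class1_name
    neg <- setdiff(c("swimming", "drifting"), pos)
    feats$activity_label[un] <- ifelse(is1_a, pos, neg)
    feats$activity_posterior[un] <- post_a
  }
  summary <- behavior_summary(feats, proc)
  structure(list(periods = feats, summary = summary, rpf = proc$rpf,
                 deployment_id = record$deployment_id),
            class = "jellytag_prediction")
}

as_qda <- function(x) {
  if (inherits(x, "jellytag_task_fit")) x$model
  else if (inherits(x, "jellytag_qda")) x
  else abort_jt("expected a jellytag_task_fit or jellytag_qda",
                "validation_error")
}

behavior_summary <- function(feats, proc) {
  n <- nrow(feats)
  n_infl <- sum(feats$tether_label == "influenced")
  un <- filter(feats, .data$tether_label == "uninfluenced")
  frac_drift <- if (nrow(un)) mean(un$activity_label == "drifting") else NA_real_
  ok <- filter(un, !.data$gimbal_excluded)
  circ <- function(pick) {
    idx <- ok$start_sample
    vals <- proc$kin$euler[[pick]][idx]
    if (!length(vals) || all(is.na(vals))) return(list(mean = NA_real_, sd = NA_real_))
    tryCatch(circular_mean_sd(vals),
             jellytag_undefined_mean = function(e) list(mean = NA_real_,
                                                        sd = NA_real_))
  }
  ch <- circ("heading"); cr <- circ("roll")
  tibble(
    deployment_id = feats$deployment_id[1],
    n_periods = n,
    fraction_influenced = n_infl / n,
    fraction_drifting_uninfluenced = frac_drift,
    n_uninfluenced = nrow(un),
    odba_norm_mean = mean(feats$odba_norm_mean),
    odba_norm_max_median = stats::median(feats$odba_norm_max),
    orientation_change_median = stats::median(ok$orientation_change,
                                              na.rm = TRUE),
    heading_circ_mean = ch$mean, heading_circ_sd = ch$sd,
    roll_circ_mean = cr$mean, roll_circ_sd = cr$sd,
    empty_uninfluenced = nrow(un) == 0L
  )
}

#' Normalized-ODBA thresholding baseline
#'
#' Evaluates the single-signal baseline that separates drifting from
#' swimming by thresholding the per-period mean normalized ODBA, under the
#' same stratified outer folds as the full method (seed-matched so the
#' per-fold AUPRCs are paired). The drifting-minority score is the
#' training-fold empirical CDF of `-odba_norm_mean` applied to the test
#' fold, a monotone map to `[0, 1]` that leaves the AUPRC of the raw ODBA
#' ranking unchanged while making the `{0.1, ..., 0.9}` EER candidates
#' quantile thresholds.
#'
#' @inheritParams train_task
#' @return a [nested_cv()] report.
#' @export
odba_threshold_baseline <- function(features, policy = training_policy(),
                                    seed = 1L, k_outer = 5) {
  rows <- eligible_training_rows(features, "activity", policy)
  if (length(unique(rows$label)) < 2L) {
    abort_jt("baseline training set lacks a class", "training_error")
  }
  scorer <- function(xtr, ytr, xte) {
    cdf <- stats::ecdf(-xtr$odba_norm_mean)
    cdf(-xte$odba_norm_mean)
  }
  nested_cv(rows[, "odba_norm_mean", drop = FALSE], rows$label,
            k_outer = k_outer, seed = seed, scorer = scorer)
}

#' Accelerometry-only variant
#'
#' The full selection-and-QDA method restricted to the 23 accelerometer
#' features (gyroscope features excluded).
#'
#' @inheritParams train_task
#' @return a `jellytag_task_fit`.
#' @export
accel_only_variant <- function(features, policy = training_policy(),
                               seed = 1L, ...) {
  cat <- feature_catalog()
  train_task(features, "activity", policy = policy, seed = seed,
             candidates = cat$feature[cat$sensor == "accel"], ...)
}

#' Majority-rule accuracy and prevalence
#'
#' The accuracy of always predicting the majority class, and the minority
#' prevalence -- the reference point that motivates evaluating imbalanced
#' classifiers by precision-recall rather than accuracy.
#'
#' @param labels binary labels (or a two-element named count vector).
#' @return a list with `accuracy` and `prevalence`.
#' @export
#' @examples
#' majority_rule_metrics(rep(c(1, 0), c(85, 4297)))
majority_rule_metrics <- function(labels) {
  if (length(labels) == 2L && !is.null(names(labels))) {
    counts <- as.numeric(labels)
  } else {
    labels <- as_binary_labels(labels)
    counts <- c(sum(labels == 0L), sum(labels == 1L))
  }
  maj <- max(counts) / sum(counts)
  list(accuracy = maj, prevalence = 1 - maj)
}

#' Annotated period counts of the original study
#'
#' The published per-category training counts (periods and seconds) from
#' the eight-deployment field campaign and the laboratory deployments,
#' provided as an input table for majority-rule arithmetic and worked
#' examples. The field recordings themselves are not publicly deposited.
#'
#' @return a tibble with columns `task`, `source`, `category`, `periods`,
#'   `seconds`.
#' @export
annotated_period_counts <- function() {
  tibble(
    task = c("tether", "tether", "activity", "activity", "activity",
             "activity"),
    source = c("in_situ", "in_situ", "laboratory", "laboratory",
               "in_situ", "in_situ"),
    category = c("influenced", "uninfluenced", "drifting", "swimming",
                 "drifting", "swimming"),
    periods = c(83L, 1245L, 68L, 3069L, 17L, 1228L),
    seconds = c(325L, 2825L, 366L, 9201L, 79L, 2740L)
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum test of a location difference between two samples, without
#' distributional assumptions. The statistic is the U for the first sample
#' (midranks for ties). For small samples (`n_a + n_b <= 12`) the
#' two-sided p value is computed by exact enumeration over all
#' `choose(n_a + n_b, n_a)` group assignments of the pooled values (valid
#' under ties); otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric samples.
#' @return a list with `statistic` (U for sample `a`) and `p_value`
#'   (two-sided).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_stat <- function(idx_a) sum(r[idx_a]) - na * (na + 1) / 2
  u <- u_stat(seq_len(na))
  if (N <= 12L) {
    combos <- utils::combn(N, na)
    us <- apply(combos, 2, u_stat)
    p <- 2 * min(mean(us <= u), mean(us >= u))
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = u, p_value = min(1, p))
}

#' Behavioral group comparisons
#'
#' The four pooled-period comparisons of the analysis: maximum normalized
#' ODBA and total orientation change, each compared (1) between annotated
#' tether-influenced and uninfluenced in-situ periods and (2) between
#' uninfluenced laboratory and uninfluenced in-situ periods, with
#' two-sided Mann-Whitney U tests. Gimbal-excluded periods are omitted
#' from the orientation-change samples; a comparison with an empty group
#' is flagged skipped.
#'
#' @param features featurized period table with `odba_norm_max`,
#'   `orientation_change`, `gimbal_excluded`, labels and `source`.
#' @return a tibble with one row per comparison: groups, sample sizes,
#'   medians, U, p value and a `skipped` flag.
#' @export
behavior_comparisons <- function(features) {
  f <- filter(as_tibble(features), .data$eligible)
  pull_vals <- function(rows, quantity) {
    if (quantity == "odba_norm_max") return(rows$odba_norm_max)
    rows <- filter(rows, !.data$gimbal_excluded)
    rows$orientation_change[!is.na(rows$orientation_change)]
  }
  specs <- list(
    list(name = "influenced_vs_uninfluenced",
         a = filter(f, .data$source == "in_situ",
                    .data$tether == "influenced"),
         b = filter(f, .data$source == "in_situ",
                    .data$tether == "uninfluenced")),
    list(name = "laboratory_vs_in_situ",
         a = filter(f, .data$source == "laboratory",
                    .data$tether == "uninfluenced"),
         b = filter(f, .data$source == "in_situ",
                    .data$tether == "uninfluenced"))
  )
  out <- list()
  for (sp in specs) {
    for (q in c("odba_norm_max", "orientation_change")) {
      va <- pull_vals(sp$a, q)
      vb <- pull_vals(sp$b, q)
      if (!length(va) || !length(vb)) {
        out[[length(out) + 1L]] <- tibble(
          comparison = sp$name, quantity = q, n_a = length(va),
          n_b = length(vb), median_a = NA_real_, median_b = NA_real_,
          statistic = NA_real_, p_value = NA_real_, skipped = TRUE)
        next
      }
      mw <- mann_whitney_u(va, vb)
      out[[length(out) + 1L]] <- tibble(
        comparison = sp$name, quantity = q, n_a = length(va),
        n_b = length(vb), median_a = stats::median(va),
        median_b = stats::median(vb), statistic = mw$statistic,
        p_value = mw$p_value, skipped = FALSE)
    }
  }
  list_rbind(out)
}
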