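# Model selection and evaluation under class imbalance: precision-recall
# curves and AUPRC, stratified folds, sequential forward selection scored by
# inner-cross-validated AUPRC, bias-free nested cross-validation, and the
# equal-error-rate threshold rule.

#' Precision-recall curve and AUPRC
#'
#' Sweeps the decision threshold over the sorted unique scores (instances
#' with `score >= threshold` are predicted positive), computing precision
#' `TP / (TP + FP)` and recall `TP / (TP + FN)` on the positive (minority)
#' class at each threshold. Precision at zero predicted positives is 1 by
#' convention; for posterior scores the curve is completed with endpoint
#' rows at thresholds 1 (precision 1, recall 0) and 0 (precision =
#' prevalence, recall = 1).
#'
#' The area under the curve is the step-wise (average-precision) integral
#' `sum_i (R_i - R_{i-1}) * P_i`, which avoids the known bias of linear
#' interpolation in precision-recall space. A random scorer has expected
#' AUPRC equal to the positive-class prevalence; a perfect separator has
#' AUPRC 1.
#'
#' @param scores numeric scores (higher = more positive), typically
#'   posteriors in `[0, 1]`.
#' @param labels binary labels; at least one positive required.
#' @return a tibble of class `jellytag_pr_curve` with columns `threshold`,
#'   `precision`, `recall` and attributes `auprc` and `prevalence`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L)
  if (P == 0L) {
    abort_jt("no positive labels: precision-recall curve is undefined",
             "curve_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores: cumulative counts at the last index of each group
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(l)[last]
  npred <- last
  precision <- tp / npred
  recall <- tp / P
  threshold <- s[last]
  auprc <- sum(diff(c(0, recall)) * precision)
  out <- tibble(threshold = threshold, precision = precision,
                recall = recall)
  if (all(scores >= 0 & scores <= 1)) {
    if (out$recall[1] > 0 && out$threshold[1] < 1) {
      out <- bind_rows(tibble(threshold = 1, precision = 1, recall = 0), out)
    }
    if (out$threshold[nrow(out)] > 0) {
      out <- bind_rows(out, tibble(threshold = 0,
                                   precision = P / length(labels),
                                   recall = 1))
    }
  }
  structure(out, auprc = auprc, prevalence = P / length(labels),
            class = c("jellytag_pr_curve", class(out)))
}

#' @rdname pr_curve
#' @export
auprc <- function(scores, labels) {
  attr(pr_curve(scores, labels), "auprc")
}

# Precision/recall at a fixed threshold grid (for point-wise curve
# averaging across folds). Zero predicted positives => precision 1.
pr_at_thresholds <- function(scores, labels, grid) {
  labels <- as_binary_labels(labels)
  P <- sum(labels == 1L)
  purrr::map(grid, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1L)
    tibble(threshold = th,
           precision = if (sum(pred) == 0L) 1 else tp / sum(pred),
           recall = tp / P)
  }) |> list_rbind()
}

#' Stratified k-fold split
#'
#' Partitions indices into `k` folds with per-fold class proportions within
#' one instance of the global proportions; deterministic given `seed`. With
#' fewer positives than folds a warning is raised and stratification is
#' best-effort.
#'
#' @param labels binary labels.
#' @param k number of folds (default 5).
#' @param seed integer seed (optional).
#' @return a list of `k` disjoint integer index vectors (test folds) whose
#'   union is all indices.
#' @export
stratified_kfold <- function(labels, k = 5, seed = NULL) {
  labels <- as_binary_labels(labels)
  n <- length(labels)
  if (n < k) abort_jt("need at least k instances", "validation_error")
  if (sum(labels == 1L) < k) {
    warn(sprintf("only %d positives for %d folds; stratification is best-effort",
                 sum(labels == 1L), k))
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- vector("list", k)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  }
  purrr::map(folds, sort)
}

#' Sequential forward selection under inner-CV AUPRC
#'
#' Greedy feature-subset growth: starting from the empty set, each step
#' scores every remaining candidate by the mean AUPRC of a QDA classifier
#' over `k_inner` stratified folds when the candidate is added to the
#' current subset, adds the best one, and stops when the best improvement
#' falls below `min_delta` (or candidates are exhausted). Candidates whose
#' QDA fit fails score 0. Ties break to the earliest candidate in
#' `candidates` order.
#'
#' @param x data frame / matrix of features.
#' @param y binary labels.
#' @param candidates candidate feature names (default: all columns of `x`).
#' @param k_inner inner folds (default 5).
#' @param min_delta minimum AUPRC improvement to continue (default 0.02).
#' @param seed seed for the inner fold split.
#' @param ridge QDA ridge (see [fit_qda()]).
#' @return character vector of selected features in selection order, with a
#'   `trace` attribute (tibble: step, feature, inner mean AUPRC).
#' @export
sfs <- function(x, y, candidates = NULL, k_inner = 5, min_delta = 0.02,
                seed = NULL, ridge = 1e-6) {
  x <- as.data.frame(x)
  y <- as_binary_labels(y)
  candidates <- candidates %||% colnames(x)
  stopifnot(length(candidates) >= 1L, all(candidates %in% colnames(x)))
  folds <- withCallingHandlers(
    stratified_kfold(y, k_inner, seed),
    warning = function(w) invokeRestart("muffleWarning"))
  score_subset <- function(feats) {
    scores <- purrr::map_dbl(folds, function(test_idx) {
      xtr <- x[-test_idx, feats, drop = FALSE]
      ytr <- y[-test_idx]
      xte <- x[test_idx, feats, drop = FALSE]
      yte <- y[test_idx]
      tryCatch({
        m <- suppressWarnings(fit_qda(xtr, ytr, ridge = ridge))
        if (sum(yte == 1L) == 0L) return(NA_real_)
        auprc(qda_posterior(m, xte), yte)
      }, error = function(e) 0)
    })
    mean(scores, na.rm = TRUE)
  }
  selected <- character(0)
  best_score <- 0
  trace <- list()
  remaining <- candidates
  while (length(remaining)) {
    cand_scores <- purrr::map_dbl(remaining, function(f) {
      score_subset(c(selected, f))
    })
    best_i <- which.max(cand_scores)   # first max wins ties
    if (cand_scores[best_i] - best_score < min_delta) break
    selected <- c(selected, remaining[best_i])
    best_score <- cand_scores[best_i]
    trace[[length(trace) + 1L]] <- tibble(
      step = length(selected), feature = remaining[best_i],
      inner_auprc = best_score)
    remaining <- remaining[-best_i]
  }
  structure(selected,
            trace = if (length(trace)) list_rbind(trace)
                    else tibble(step = integer(), feature = character(),
                                inner_auprc = numeric()))
}

#' Equal-error-rate threshold
#'
#' From an averaged precision-recall curve evaluated on a threshold grid,
#' picks the candidate threshold (default `{0.1, ..., 0.9}`) whose
#' precision and recall are closest to each other; ties go to the higher
#' threshold.
#'
#' @param avg_curve tibble with columns `threshold`, `precision`, `recall`
#'   covering the candidate thresholds.
#' @param candidates candidate thresholds.
#' @return the selected threshold.
#' @export
eer_threshold <- function(avg_curve, candidates = seq(0.1, 0.9, by = 0.1)) {
  rows <- purrr::map_dbl(candidates, function(th) {
    i <- which.min(abs(avg_curve$threshold - th))
    abs(avg_curve$precision[i] - avg_curve$recall[i])
  })
  best <- min(rows)
  max(candidates[rows <= best + 1e-12])
}

#' Nested cross-validated evaluation
#'
#' For each of `k_outer` stratified outer folds, feature selection (SFS
#' with `k_inner` inner folds) is run on the training portion only; a QDA
#' classifier with the selected features is then fitted on the training
#' portion and scored on the held-out fold. Test indices are never touched
#' during selection, removing the optimism bias of selecting features on
#' the full dataset. Per-fold test-side precision-recall curves are
#' evaluated on a fixed threshold grid and averaged point-wise; the
#' equal-error-rate threshold chosen from the averaged curve yields
#' per-fold precision, recall and accuracy.
#'
#' A custom `scorer` (function of `x_train, y_train, x_test` returning test
#' scores in `[0, 1]`) replaces the SFS + QDA route, which is how the
#' single-signal baseline is evaluated under identical folds.
#'
#' @inheritParams sfs
#' @param k_outer,k_inner outer / inner fold counts (default 5).
#' @param seed seed fixing the outer folds and, per fold, the inner folds.
#' @param scorer optional custom scoring function.
#' @param grid threshold grid for curve averaging.
#' @return an object of class `jellytag_cv_report`: per-fold AUPRC, mean
#'   and standard error, the averaged PR curve, per-fold selected features,
#'   the EER threshold and per-fold EER-threshold metrics.
#' @export
nested_cv <- function(x, y, candidates = NULL, k_outer = 5, k_inner = 5,
                      min_delta = 0.02, seed = NULL, ridge = 1e-6,
                      scorer = NULL, grid = seq(0.01, 0.99, by = 0.01)) {
  x <- as.data.frame(x)
  y <- as_binary_labels(y)
  folds <- stratified_kfold(y, k_outer, seed)
  fold_out <- purrr::imap(folds, function(test_idx, f) {
    xtr <- x[-test_idx, , drop = FALSE]
    ytr <- y[-test_idx]
    xte <- x[test_idx, , drop = FALSE]
    yte <- y[test_idx]
    inner_seed <- if (is.null(seed)) NULL else (seed + f) %% 2147483647
    if (is.null(scorer)) {
      sel <- sfs(xtr, ytr, candidates = candidates, k_inner = k_inner,
                 min_delta = min_delta, seed = inner_seed, ridge = ridge)
      sel <- as.character(sel)
      if (!length(sel)) {    # no informative feature: fall back to best single
        tr <- attr(sfs(xtr, ytr, candidates = candidates, k_inner = k_inner,
                       min_delta = 0, seed = inner_seed, ridge = ridge),
                   "trace")
        sel <- tr$feature[1]
      }
      m <- suppressWarnings(fit_qda(xtr[, sel, drop = FALSE], ytr,
                                    ridge = ridge))
      sc <- qda_posterior(m, xte[, sel, drop = FALSE])
    } else {
      sel <- character(0)
      sc <- scorer(xtr, ytr, xte)
    }
    list(auprc = auprc(sc, yte),
         curve = pr_at_thresholds(sc, yte, grid),
         selected = sel, scores = sc, labels = yte)
  })
  fold_auprc <- map_dbl(fold_out, "auprc")
  avg_curve <- purrr::map(fold_out, "curve") |>
    list_rbind() |>
    group_by(.data$threshold) |>
    summarise(precision = mean(.data$precision),
              recall = mean(.data$recall), .groups = "drop")
  eer <- eer_threshold(avg_curve)
  fold_metrics <- purrr::imap(fold_out, function(fo, f) {
    pred <- fo$scores >= eer
    tp <- sum(pred & fo$labels == 1L)
    tibble(
      fold = f, auprc = fo$auprc,
      precision = if (sum(pred) == 0L) 1 else tp / sum(pred),
      recall = tp / sum(fo$labels == 1L),
      accuracy = mean(pred == (fo$labels == 1L))
    )
  }) |> list_rbind()
  k <- length(folds)
  structure(
    list(fold_auprc = fold_auprc,
         mean_auprc = mean(fold_auprc),
         se_auprc = sd(fold_auprc) / sqrt(k),
         avg_curve = avg_curve,
         selected = purrr::map(fold_out, "selected"),
         eer_threshold = eer,
         fold_metrics = fold_metrics,
         mean_precision = mean(fold_metrics$precision),
         se_precision = sd(fold_metrics$precision) / sqrt(k),
         mean_recall = mean(fold_metrics$recall),
         se_recall = sd(fold_metrics$recall) / sqrt(k),
         mean_accuracy = mean(fold_metrics$accuracy),
         se_accuracy = sd(fold_metrics$accuracy) / sqrt(k),
         k = k, seed = seed,
         prevalence = mean(y == 1L)),
    class = "jellytag_cv_report"
  )
}

#' @export
print.jellytag_cv_report <- function(x, ...) {
  cat(sprintf(
    "<jellytag_cv_report> %d-fold nested CV\n  AUPRC %.3f +/- %.3f (chance %.3f)\n  EER threshold %.1f: precision %.3f +/- %.3f, recall %.3f +/- %.3f, accuracy %.3f\n",
    x$k, x$mean_auprc, x$se_auprc, x$prevalence, x$eer_threshold,
    x$mean_precision, x$se_precision, x$mean_recall, x$se_recall,
    x$mean_accuracy))
  invisible(x)
}

#' Tidy / glance a cross-validation report
#'
#' @param x a `jellytag_cv_report`.
#' @param ... unused.
#' @return `tidy()`: one row per outer fold with AUPRC and EER-threshold
#'   metrics plus the selected features; `glance()`: a one-row summary.
#' @export
tidy.jellytag_cv_report <- function(x, ...) {
  out <- x$fold_metrics
  out$selected <- map_chr(x$selected, paste, collapse = "+")
  out
}

#' @rdname tidy.jellytag_cv_report
#' @export
glance.jellytag_cv_report <- function(x, ...) {
  tibble(
    k = x$k, mean_auprc = x$mean_auprc, se_auprc = x$se_auprc,
    eer_threshold = x$eer_threshold,
    mean_precision = x$mean_precision, se_precision = x$se_precision,
    mean_recall = x$mean_recall, se_recall = x$se_recall,
    mean_accuracy = x$mean_accuracy, se_accuracy = x$se_accuracy,
    prevalence = x$prevalence
  )
}

#' Serialize a CV report to JSON and its averaged curve to CSV
#'
#' @param report a `jellytag_cv_report`.
#' @param path_json,path_csv output paths (`NULL` to skip either).
#' @export
write_cv_report <- function(report, path_json, path_csv = NULL) {
  out <- report[c("fold_auprc", "mean_auprc", "se_auprc", "selected",
                  "eer_threshold", "mean_precision", "se_precision",
                  "mean_recall", "se_recall", "mean_accuracy",
                  "se_accuracy", "k", "prevalence")]
  out$fold_metrics <- report$fold_metrics
  jsonlite::write_json(out, path_json, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  if (!is.null(path_csv)) {
    readr::write_csv(report$avg_curve, path_csv, progress = FALSE)
  }
  invisible(report)
}
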