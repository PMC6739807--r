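# Precision-recall machinery, stratified folds, forward selection, nested
# cross-validation and the equal-error-rate threshold rule.

test_that("the PR sweep matches the brute-force confusion-matrix oracle", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.1, 0.5))
    if (sum(labels) == 0) labels[1] <- 1L
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    crv <- pr_curve(scores, labels)
    orc <- oracle_pr(scores, labels)
    core <- crv[crv$threshold %in% scores, ]   # drop the endpoint rows
    expect_equal(nrow(core), nrow(orc))
    expect_equal(core$precision, orc$precision, tolerance = 1e-12)
    expect_equal(core$recall, orc$recall, tolerance = 1e-12)
    expect_equal(attr(crv, "auprc"), oracle_auprc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUPRC anchors: perfect separation, perfect inversion, chance", {
  labels <- rep(c(1, 0), c(10, 90))
  perfect <- c(runif(10, 0.8, 1), runif(90, 0, 0.5))
  expect_equal(auprc(perfect, labels), 1)
  inverted <- 1 - perfect
  expect_lt(auprc(inverted, labels), 0.15)
  expect_error(pr_curve(runif(10), rep(0, 10)), class = "jellytag_curve_error")
  # curve endpoints for posterior scores
  crv <- pr_curve(perfect, labels)
  expect_equal(crv$recall[1], 0)
  expect_equal(crv$precision[1], 1)
  expect_equal(crv$recall[nrow(crv)], 1)
  expect_equal(crv$precision[nrow(crv)], 0.1)
  expect_equal(attr(crv, "prevalence"), 0.1)
})

test_that("stratified folds partition the data and preserve class balance", {
  set.seed(31)
  labels <- rbinom(200, 1, 0.2)
  folds <- stratified_kfold(labels, k = 5, seed = 7)
  expect_length(folds, 5)
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, 1:200)                        # disjoint and complete
  pos_per_fold <- vapply(folds, function(f) sum(labels[f] == 1), numeric(1))
  expect_lte(diff(range(pos_per_fold)), 1)
  n_per_fold <- lengths(folds)
  expect_lte(diff(range(n_per_fold)), 2)
  expect_identical(folds, stratified_kfold(labels, k = 5, seed = 7))
  expect_false(identical(folds, stratified_kfold(labels, k = 5, seed = 8)))
  expect_warning(stratified_kfold(rep(c(1, 0), c(3, 47)), k = 5, seed = 1),
                 "best-effort")
})

test_that("forward selection finds the informative feature and stops on noise", {
  set.seed(41)
  n <- 300
  y <- rbinom(n, 1, 0.25)
  x <- data.frame(
    noise1 = rnorm(n), noise2 = rnorm(n),
    signal = rnorm(n, mean = 4 * y),
    noise3 = rnorm(n)
  )
  sel <- sfs(x, y, seed = 1)
  expect_identical(sel[1], "signal")
  expect_lte(length(sel), 2)
  tr <- attr(sel, "trace")
  expect_equal(tr$feature[1], "signal")
  expect_gt(tr$inner_auprc[1], 0.9)
  # candidate restriction is honored
  sel2 <- sfs(x, y, candidates = c("noise1", "noise2"), seed = 1)
  expect_true(all(sel2 %in% c("noise1", "noise2")))
  expect_error(sfs(x, y, candidates = "absent"), "candidates")
})

test_that("the EER rule picks the precision/recall crossing, ties upward", {
  curve <- tibble::tibble(
    threshold = seq(0.01, 0.99, by = 0.01),
    precision = seq(0.01, 0.99, by = 0.01),   # increasing
    recall = rev(seq(0.01, 0.99, by = 0.01))  # decreasing; crossing at 0.5
  )
  expect_equal(eer_threshold(curve), 0.5)
  flat <- tibble::tibble(threshold = seq(0.01, 0.99, by = 0.01),
                         precision = 1, recall = 1)
  expect_equal(eer_threshold(flat), 0.9)      # all tied: highest candidate
})

test_that("nested cross-validation is deterministic and scores separable data highly", {
  d <- simulate_gaussian_features(c(0, 0, 0), c(5, 0, 0), diag(3), diag(3),
                                  alpha = 0.2, n = 250, seed = 13)
  x <- d[paste0("f", 1:3)]
  r1 <- nested_cv(x, d$label, seed = 3, k_outer = 3, k_inner = 3)
  r2 <- nested_cv(x, d$label, seed = 3, k_outer = 3, k_inner = 3)
  expect_equal(r1$fold_auprc, r2$fold_auprc)
  expect_identical(r1$selected, r2$selected)
  expect_gt(r1$mean_auprc, 0.95)
  expect_equal(nrow(r1$fold_metrics), 3)
  expect_true(all(unlist(r1$selected) %in% names(x)))
  expect_true(r1$eer_threshold %in% seq(0.1, 0.9, by = 0.1))
  expect_equal(r1$prevalence, mean(d$label))
  # report accessors
  expect_equal(nrow(tidy(r1)), 3)
  expect_equal(glance(r1)$mean_auprc, r1$mean_auprc)
})

test_that("a custom scorer replaces selection under identical folds", {
  d <- simulate_gaussian_features(0, 3, matrix(1), matrix(1),
                                  alpha = 0.3, n = 200, seed = 17)
  scorer <- function(xtr, ytr, xte) stats::ecdf(xtr$f1)(xte$f1)
  r <- nested_cv(d["f1"], d$label, seed = 2, k_outer = 4, scorer = scorer)
  expect_gt(r$mean_auprc, 0.8)
  expect_true(all(lengths(r$selected) == 0))
})

test_that("cross-validation reports serialize to JSON and CSV", {
  d <- simulate_gaussian_features(0, 3, matrix(1), matrix(1),
                                  alpha = 0.3, n = 150, seed = 19)
  r <- nested_cv(d["f1"], d$label, seed = 2, k_outer = 3, k_inner = 3)
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(r, pj, pc)
  j <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(j$mean_auprc, r$mean_auprc, tolerance = 1e-12)
  expect_equal(j$eer_threshold, r$eer_threshold)
  curve <- readr::read_csv(pc, show_col_types = FALSE)
  expect_equal(nrow(curve), nrow(r$avg_curve))
})
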