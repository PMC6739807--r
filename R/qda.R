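# Quadratic discriminant analysis: each class is modeled as a multivariate
# Gaussian with its own mean and covariance, plus a Bernoulli class prior;
# decisions threshold the Bayes posterior p(y = 1 | x).

#' Fit a quadratic discriminant classifier
#'
#' Maximum-likelihood fit of the two-class Gaussian generative model: class
#' means are the sample means, class covariances are the MLE (divide by
#' `n_c`) sample covariances (optionally the unbiased `n_c - 1` version),
#' and the class-1 prior `alpha` is the training proportion of class 1. A
#' small relative ridge `ridge * tr(Sigma_c) / p` is added to each
#' covariance diagonal to guard against numerically singular inversions
#' from highly correlated features.
#'
#' @param x data frame or matrix of features (rows = instances).
#' @param y binary labels (0/1, logical, or factor with two levels where
#'   the second level is class 1); both classes must be present.
#' @param ridge relative ridge added to each covariance (default `1e-6`).
#' @param unbiased use the `1/(n_c - 1)` covariance instead of the MLE.
#' @param threshold decision threshold on the class-1 posterior (default
#'   0.5); ties classify as class 1.
#' @param class1_name name of class 1 (by convention the minority
#'   category, e.g. `"drifting"` for the activity task).
#' @return an object of class `jellytag_qda` with elements `mu0`, `mu1`,
#'   `sigma0`, `sigma1`, `alpha`, `feature_names`, `threshold`,
#'   `class1_name`, `n0`, `n1`.
#' @export
fit_qda <- function(x, y, ridge = 1e-6, unbiased = FALSE, threshold = 0.5,
                    class1_name = "1") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_labels(y)
  if (length(y) != nrow(x)) abort_jt("x and y lengths differ", "fit_error")
  if (length(unique(y)) < 2L) {
    abort_jt("both classes must be present in the training data",
             "fit_error")
  }
  p <- ncol(x)
  fit_class <- function(xc) {
    n <- nrow(xc)
    mu <- colMeans(xc)
    cen <- sweep(xc, 2, mu)
    sig <- crossprod(cen) / if (unbiased) max(1, n - 1) else n
    sig <- sig + diag(ridge * sum(diag(sig)) / p, p)
    if (n < p + 1L) {
      warn(sprintf("class with %d instances has fewer than p + 1 = %d; covariance is poorly determined",
                   n, p + 1L))
    }
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) {
      abort_jt("class covariance is singular even after ridge regularization",
               "numerical_error")
    }
    list(mu = mu, sigma = sig, chol = ch, n = n)
  }
  c0 <- fit_class(x[y == 0L, , drop = FALSE])
  c1 <- fit_class(x[y == 1L, , drop = FALSE])
  structure(
    list(mu0 = c0$mu, mu1 = c1$mu, sigma0 = c0$sigma, sigma1 = c1$sigma,
         chol0 = c0$chol, chol1 = c1$chol,
         alpha = c1$n / (c0$n + c1$n),
         feature_names = colnames(x) %||% paste0("f", seq_len(p)),
         threshold = threshold, class1_name = class1_name,
         n0 = c0$n, n1 = c1$n, ridge = ridge),
    class = "jellytag_qda"
  )
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) {
    abort_jt("labels must be binary (0/1)", "fit_error")
  }
  y
}

# Row-wise Gaussian log density from a precomputed Cholesky factor.
log_mvnorm_chol <- function(x, mu, ch) {
  z <- backsolve(ch, t(sweep(x, 2, mu)), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) -
    0.5 * ncol(x) * log(2 * pi)
}

#' Class-1 posterior probability
#'
#' `p(y = 1 | x)` under the fitted model, computed in log space so extreme
#' likelihood ratios neither underflow nor overflow.
#'
#' @param model a [fit_qda()] fit.
#' @param x a numeric vector (one instance) or matrix / data frame of
#'   instances; columns are matched to `model$feature_names` when named.
#' @return numeric vector of posteriors in `[0, 1]`.
#' @export
qda_posterior <- function(model, x) {
  x <- as_model_matrix(model, x)
  l1 <- log(model$alpha) + log_mvnorm_chol(x, model$mu1, model$chol1)
  l0 <- log(1 - model$alpha) + log_mvnorm_chol(x, model$mu0, model$chol0)
  1 / (1 + exp(pmin(700, pmax(-700, l0 - l1))))
}

as_model_matrix <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.data.frame(x)) {
    if (all(model$feature_names %in% names(x))) {
      x <- x[model$feature_names]
    }
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  if (ncol(x) != length(model$mu0)) {
    abort_jt("feature dimension does not match the fitted model",
             "validation_error")
  }
  x
}

#' Threshold classification
#'
#' Classifies instances as class 1 when the posterior is greater than or
#' equal to the model threshold (ties go to class 1).
#'
#' @inheritParams qda_posterior
#' @param threshold optional override of `model$threshold`.
#' @return integer vector of 0/1 labels.
#' @export
qda_classify <- function(model, x, threshold = NULL) {
  th <- threshold %||% model$threshold
  as.integer(qda_posterior(model, x) >= th)
}

#' @export
#' @param object a `jellytag_qda` model.
#' @param newdata instances to score.
#' @param type `"posterior"` (default) or `"class"`.
#' @param ... unused.
#' @rdname qda_posterior
predict.jellytag_qda <- function(object, newdata,
                                 type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (type == "posterior") qda_posterior(object, newdata)
  else qda_classify(object, newdata)
}

#' @export
print.jellytag_qda <- function(x, ...) {
  cat(sprintf(
    "<jellytag_qda> p = %d features, alpha = %.4f (class 1 = '%s'), threshold = %.2f\n",
    length(x$mu0), x$alpha, x$class1_name, x$threshold))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted QDA model
#'
#' @param x a `jellytag_qda` model.
#' @param ... unused.
#' @return one row per feature and class with the fitted mean and marginal
#'   standard deviation.
#' @export
tidy.jellytag_qda <- function(x, ...) {
  p <- length(x$mu0)
  tibble(
    feature = rep(x$feature_names, 2L),
    class = rep(c(0L, 1L), each = p),
    mean = c(x$mu0, x$mu1),
    sd = c(sqrt(diag(x$sigma0)), sqrt(diag(x$sigma1)))
  )
}

#' @rdname tidy.jellytag_qda
#' @export
glance.jellytag_qda <- function(x, ...) {
  tibble(p = length(x$mu0), alpha = x$alpha, threshold = x$threshold,
         n0 = x$n0, n1 = x$n1, class1 = x$class1_name)
}

#' Serialize / restore a QDA model as JSON
#'
#' @param model a `jellytag_qda` model.
#' @param path output path.
#' @export
write_qda_json <- function(model, path) {
  out <- list(
    mu0 = unname(model$mu0), mu1 = unname(model$mu1),
    sigma0 = unname(model$sigma0), sigma1 = unname(model$sigma1),
    alpha = model$alpha, feature_names = model$feature_names,
    threshold = model$threshold, class1_name = model$class1_name,
    n0 = model$n0, n1 = model$n1, ridge = model$ridge
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(model)
}

#' @rdname write_qda_json
#' @export
read_qda_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(
    mu0 = as.numeric(j$mu0), mu1 = as.numeric(j$mu1),
    sigma0 = as.matrix(j$sigma0), sigma1 = as.matrix(j$sigma1),
    alpha = j$alpha, feature_names = j$feature_names,
    threshold = j$threshold, class1_name = j$class1_name,
    n0 = j$n0, n1 = j$n1, ridge = j$ridge
  )
  m$chol0 <- chol(m$sigma0)
  m$chol1 <- chol(m$sigma1)
  names(m$mu0) <- names(m$mu1) <- m$feature_names
  structure(m, class = "jellytag_qda")
}
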