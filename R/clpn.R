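#' Cross-validated lasso logistic regression with the one-SE rule
#'
#' Fits the full-data lasso path, then estimates out-of-sample binomial
#' deviance by k-fold cross-validation on the same lambda grid.  Folds are
#' assigned by seeded permutation, stratified by the outcome so that every
#' fold contains both classes even at low prevalence; fold sizes differ by
#' at most one within each class.  lambda_min minimises the mean CV
#' deviance; lambda_1SE is the largest lambda whose mean CV deviance lies
#' within one standard error (SD of the fold deviances / sqrt(k)) of that
#' minimum — the parsimonious choice used for cross-lagged estimation.
#'
#' @param y binary response vector (not constant).
#' @param X predictor matrix, rows aligned with `y`.
#' @param k_folds number of folds (default 10); requires n >= k_folds.
#' @param seed integer seed for fold assignment.
#' @param n_lambda,lambda_min_ratio,standardize,thresh path settings, as in
#'   [nodewise_lasso_path()].
#' @return A list of class `cv_lasso_fit`: `lambda`, `cv_deviance` (mean
#'   held-out deviance per lambda), `cv_se`, `lambda_min`, `lambda_1se`,
#'   their indices, `coef_min`/`coef_1se` (intercept + slopes), `foldid`.
#' @export
cv_lasso_logistic <- function(y, X, k_folds = 10, seed = 1, n_lambda = 100,
                              lambda_min_ratio = 0.01, standardize = FALSE,
                              thresh = 1e-9) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("y and X must be row-aligned")
  if (var(y) == 0) stop("constant outcome")
  if (n < k_folds) stop("need n >= k_folds")
  master <- lasso_logistic_path(y, X, n_lambda = n_lambda,
                                lambda_min_ratio = lambda_min_ratio,
                                standardize = standardize, thresh = thresh)
  lambda <- master$lambda
  foldid <- make_stratified_folds(y, k_folds, seed)
  fold_dev <- matrix(NA_real_, length(lambda), k_folds)
  for (f in seq_len(k_folds)) {
    hold <- foldid == f
    fit_f <- lasso_logistic_path(y[!hold], X[!hold, , drop = FALSE],
                                 lambda = lambda, standardize = standardize,
                                 thresh = thresh)
    eta <- matrix(fit_f$a0, sum(hold), length(lambda), byrow = TRUE) +
      X[hold, , drop = FALSE] %*% fit_f$beta
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    yy <- y[hold]
    fold_dev[, f] <- colMeans(-2 * (yy * log(mu) + (1 - yy) * log(1 - mu)))
  }
  cv_mean <- rowMeans(fold_dev)
  cv_se <- apply(fold_dev, 1, sd) / sqrt(k_folds)
  i_min <- which.min(cv_mean)                     # ties -> larger lambda
  cutoff <- cv_mean[i_min] + cv_se[i_min]
  i_1se <- which(cv_mean <= cutoff)[1L]           # lambda is descending
  coefs <- function(i) {
    c(intercept = master$a0[i], master$beta[, i])
  }
  structure(
    list(lambda = lambda, cv_deviance = cv_mean, cv_se = cv_se,
         fold_deviance = fold_dev,
         index_min = i_min, index_1se = i_1se,
         lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
         coef_min = coefs(i_min), coef_1se = coefs(i_1se),
         foldid = foldid, seed = seed),
    class = "cv_lasso_fit")
}

# Outcome-stratified fold assignment by seeded permutation; retries with a
# derived sub-seed (logged via warning) if any fold ends up with a constant
# outcome, which can happen only at very small n.
make_stratified_folds <- function(y, k_folds, seed, max_tries = 10) {
  n <- length(y)
  for (try in seq_len(max_tries)) {
    sub_seed <- if (try == 1) seed else derive_seeds(seed, try)[try]
    foldid <- integer(n)
    with_seed(sub_seed, {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        foldid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
      }
    })
    degenerate <- any(vapply(seq_len(k_folds), function(f) {
      yy <- y[foldid == f]
      length(yy) == 0L || var(yy) == 0
    }, logical(1)))
    if (!degenerate) {
      if (try > 1) warning("refolded with sub-seed after degenerate fold")
      return(foldid)
    }
  }
  warning("could not avoid degenerate folds; using last assignment")
  foldid
}

#' Select the one-SE lambda from a CV curve
#'
#' Pure-rule helper, exposed for verification: given a descending lambda
#' grid, mean CV deviances and the SE at the minimum, returns the index of
#' the largest lambda whose mean deviance is within one SE of the minimum.
#'
#' @param lambda descending penalty grid.
#' @param cv_mean mean CV deviance per lambda.
#' @param se_at_min standard error of the CV deviance at the minimising
#'   lambda.
#' @return Integer index into `lambda`.
#' @export
one_se_index <- function(lambda, cv_mean, se_at_min) {
  stopifnot(length(lambda) == length(cv_mean), !is.unsorted(rev(lambda)))
  i_min <- which.min(cv_mean)
  which(cv_mean <= cv_mean[i_min] + se_at_min)[1L]
}

#' Estimate a cross-lagged panel network
#'
#' Fits one cross-validated lasso logistic regression per Wave-2 outcome,
#' with all Wave-1 items as predictors, and assembles the directed network
#' from the coefficients at lambda_1SE (or lambda_min).  Column j of the
#' coefficient matrix holds the effects on outcome j; the diagonal is the
#' autoregressive effect of each item on itself.  A constant Wave-2 outcome
#' yields a zero column with a warning.
#'
#' @param w1,w2 [binary_symptoms()] matrices for Waves 1 and 2, same
#'   subjects in the same row order.
#' @param seed master seed; per-outcome fold seeds are derived from it.
#' @param k_folds folds for cross-validation (default 10).
#' @param rule `"1se"` (default) or `"min"` penalty choice.
#' @param n_lambda,lambda_min_ratio,standardize,thresh path settings.
#' @return A [clpn_network()].
#' @export
fit_clpn <- function(w1, w2, seed = 1, k_folds = 10, rule = c("1se", "min"),
                     n_lambda = 100, lambda_min_ratio = 0.01,
                     standardize = FALSE, thresh = 1e-9) {
  rule <- match.arg(rule)
  x1 <- unclass(as.matrix(w1))
  x2 <- unclass(as.matrix(w2))
  if (!identical(dim(x1), dim(x2))) stop("waves must have matching shape")
  p <- ncol(x1)
  labels <- colnames(x1)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  seeds <- derive_seeds(seed, p)
  B <- matrix(0, p, p)
  intercepts <- numeric(p)
  lambda_info <- data.frame(item = labels, lambda_min = NA_real_,
                            lambda_1se = NA_real_)
  for (j in seq_len(p)) {
    yj <- x2[, j]
    if (var(yj) == 0) {
      warning(sprintf("Wave-2 outcome %d constant; zero column", j))
      intercepts[j] <- qlogis((sum(yj) + 0.5) / (length(yj) + 1))
      next
    }
    cvfit <- cv_lasso_logistic(yj, x1, k_folds = k_folds, seed = seeds[j],
                               n_lambda = n_lambda,
                               lambda_min_ratio = lambda_min_ratio,
                               standardize = standardize, thresh = thresh)
    cf <- if (rule == "1se") cvfit$coef_1se else cvfit$coef_min
    intercepts[j] <- cf[1L]
    B[, j] <- cf[-1L]
    lambda_info$lambda_min[j] <- cvfit$lambda_min
    lambda_info$lambda_1se[j] <- cvfit$lambda_1se
  }
  clpn_network(B, intercepts, item_labels = labels,
               lambda_info = lambda_info, fold_seed = seed)
}
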