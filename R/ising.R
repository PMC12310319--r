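#' Extended Bayesian Information Criterion
#'
#' EBIC = -2 loglik + k log(n) + 2 gamma k log(p_candidates), where k counts
#' the active slope coefficients (the intercept is not penalised and not
#' counted) and p_candidates is the number of candidate predictors.
#' `gamma = 0` reduces to the ordinary BIC; `gamma = 0.5` is the standard
#' sparsity/fit trade-off for nodewise network estimation.
#'
#' @param loglik model log-likelihood.
#' @param k_active number of nonzero slope coefficients.
#' @param n sample size.
#' @param p_candidates number of candidate predictors.
#' @param gamma EBIC hyperparameter, >= 0.
#' @return Scalar EBIC value (vectorised over its arguments).
#' @export
ebic <- function(loglik, k_active, n, p_candidates, gamma = 0.5) {
  stopifnot(all(n >= 1), all(gamma >= 0))
  -2 * loglik + k_active * log(n) + 2 * gamma * k_active * log(p_candidates)
}

#' L1-penalised logistic path for one node
#'
#' Fits the lasso-regularised logistic regression of a binary outcome on a
#' set of binary predictors along a log-spaced lambda grid descending from
#' lambda_max (the smallest penalty at which all slopes are zero), and
#' scores every grid point by EBIC.  The path is computed by iteratively
#' reweighted least squares with cyclic coordinate descent (compiled,
#' warm-started along the grid; the intercept is unpenalised).
#'
#' @param y binary response vector (not constant).
#' @param X predictor matrix, rows aligned with `y`.
#' @param n_lambda number of grid points (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#'   (default 0.01).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param standardize standardise predictors before penalisation? Binary
#'   predictors are left on their natural scale by default so coefficients
#'   are log-odds per endorsement.
#' @param thresh coordinate-descent convergence threshold.
#' @return A list of class `lasso_path_fit`: `lambda` (descending), `beta`
#'   (predictors x lambda), `intercepts`, `loglik`, `k_active`, `ebic`,
#'   `selected` (index minimising EBIC; ties broken toward larger lambda).
#' @export
nodewise_lasso_path <- function(y, X, n_lambda = 100, lambda_min_ratio = 0.01,
                                gamma = 0.5, standardize = FALSE,
                                thresh = 1e-9) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("y and X must be row-aligned")
  if (var(y) == 0) stop("constant outcome: nodewise model undefined")
  fit <- lasso_logistic_path(y, X, n_lambda = n_lambda,
                             lambda_min_ratio = lambda_min_ratio,
                             standardize = standardize, thresh = thresh)
  n <- length(y)
  # binomial log-likelihood = -deviance / 2 (saturated loglik is zero)
  loglik <- -fit$dev / 2
  k_active <- colSums(fit$beta != 0)
  crit <- ebic(loglik, k_active, n, p_candidates = ncol(X), gamma = gamma)
  structure(
    list(lambda = fit$lambda, beta = fit$beta,
         intercepts = as.numeric(fit$a0),
         loglik = loglik, k_active = k_active, ebic = crit,
         selected = which.min(crit),  # lambda descending: first min = largest
         gamma = gamma),
    class = "lasso_path_fit")
}

#' Estimate a cross-sectional Ising network
#'
#' Nodewise l1-penalised logistic regression with EBIC model selection: each
#' item is regressed on all others along a lasso path, the penalty minimising
#' EBIC (hyperparameter `gamma`, default 0.5) is selected per node, and the
#' resulting asymmetric coefficient matrix is symmetrised.  Under the
#' default AND rule an edge is retained only when both directed coefficients
#' are nonzero (their average is taken); under the OR rule one nonzero
#' coefficient suffices and the absent one counts as zero in the average.
#' Node thresholds are the selected intercepts.  Items with no variance are
#' isolated (all incident edges zero) with a warning.
#'
#' @param m a [binary_symptoms()] matrix with n > p.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param rule symmetrisation rule, `"and"` (default) or `"or"`.
#' @param n_lambda,lambda_min_ratio,standardize,thresh forwarded to
#'   [nodewise_lasso_path()].
#' @return An [ising_network()].
#' @export
fit_ising <- function(m, gamma = 0.5, rule = c("and", "or"), n_lambda = 100,
                      lambda_min_ratio = 0.01, standardize = FALSE,
                      thresh = 1e-9) {
  rule <- match.arg(rule)
  x <- unclass(as.matrix(m))
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("estimation requires n > p")
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  beta <- matrix(0, p, p)           # beta[i, j]: effect of i in node-j model
  thresholds <- numeric(p)
  sel_lambda <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    yj <- x[, j]
    if (var(yj) == 0) {
      warning(sprintf("item %d ('%s') is constant; node isolated", j,
                      labels[j]))
      # continuity-corrected log-odds keeps the threshold finite
      thresholds[j] <- qlogis((sum(yj) + 0.5) / (n + 1))
      next
    }
    path <- nodewise_lasso_path(yj, x[, -j, drop = FALSE],
                                n_lambda = n_lambda,
                                lambda_min_ratio = lambda_min_ratio,
                                gamma = gamma, standardize = standardize,
                                thresh = thresh)
    s <- path$selected
    beta[-j, j] <- path$beta[, s]
    thresholds[j] <- path$intercepts[s]
    sel_lambda[j] <- path$lambda[s]
  }
  both <- (beta != 0) & (t(beta) != 0)
  either <- (beta != 0) | (t(beta) != 0)
  avg <- (beta + t(beta)) / 2
  W <- avg * (if (rule == "and") both else either)
  diag(W) <- 0
  ising_network(W, thresholds, item_labels = labels,
                estimation_meta = list(
                  gamma = gamma, rule = rule, n = n,
                  n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                  standardize = standardize, selected_lambda = sel_lambda))
}

#' Global strength of an undirected network
#'
#' Sum of absolute edge weights over the unique (upper-triangle) edges.
#'
#' @param net an [ising_network()] or a plain symmetric matrix.
#' @return Scalar global strength.
#' @export
global_strength <- function(net) {
  w <- if (inherits(net, "ising_network")) net$weights else as.matrix(net)
  sum(abs(upper_tri_vec(w)))
}
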