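# Internal driver for the l1-penalised logistic path (compiled coordinate
# descent).  Builds the log-spaced lambda grid from lambda_max (the smallest
# penalty at which every slope is exactly zero, |x_j'(y - ybar)| / n at its
# maximum) unless an explicit grid is supplied, optionally standardises the
# predictors glmnet-style (centre, population SD scale) and returns
# coefficients on the original scale.
lasso_logistic_path <- function(y, X, n_lambda = 100, lambda_min_ratio = 0.01,
                                standardize = FALSE, thresh = 1e-9,
                                lambda = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (nrow(X) != n) stop("y and X must be row-aligned")
  ybar <- mean(y)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- sqrt(colMeans(X^2) - ctr^2)
    scl[scl == 0] <- 1
    Xw <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  } else {
    Xw <- X
  }
  if (is.null(lambda)) {
    lambda_max <- max(abs(crossprod(Xw, y - ybar))) / n
    # nudge so the first grid point sits strictly above every score
    lambda <- exp(seq(log(lambda_max * (1 + 1e-6)),
                      log(lambda_max * lambda_min_ratio),
                      length.out = n_lambda))
  }
  fit <- .cd_logistic_path(Xw, y, lambda, thresh)
  beta <- fit$beta
  a0 <- fit$a0
  if (standardize) {
    beta <- beta / scl
    a0 <- a0 - drop(crossprod(ctr, beta))
  }
  nulldev <- -2 * sum(y * log(ybar) + (1 - y) * log(1 - ybar))
  list(lambda = lambda, beta = beta, a0 = a0, dev = fit$dev,
       nulldev = nulldev)
}
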