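# Shared fixtures, built in code at test time.

# Small 4-node Ising parameter set with mixed signs, used wherever exact
# enumeration is the oracle.
toy_ising4 <- function() {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1.0
  W[2, 3] <- W[3, 2] <- -0.8
  W[3, 4] <- W[4, 3] <- 0.6
  ising_params(W, thresholds = c(-0.5, 0.2, 0, -0.3))
}

# Write a toy two-wave CSV panel and return its path.
write_toy_panel_csv <- function(path = tempfile(fileext = ".csv"),
                                incomplete_rows = 0) {
  set.seed(42)
  n <- 5 + incomplete_rows
  df <- data.frame(id = sprintf("s%02d", seq_len(n)))
  for (w in 1:2) for (j in 1:10) {
    df[[sprintf("w%d_d%d", w, j)]] <- sample(0:3, n, replace = TRUE)
  }
  if (incomplete_rows > 0) {
    df$w1_d3[seq_len(incomplete_rows)] <- NA
  }
  write.csv(df, path, row.names = FALSE)
  path
}

# Random symmetric zero-diagonal weight matrix.
random_weights <- function(p, seed = 1, density = 0.4, lo = 0.3, hi = 1.2) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- sample(ut, ceiling(density * length(ut)))
  W[on] <- runif(length(on), lo, hi) * sample(c(-1, 1), length(on),
                                              replace = TRUE, prob = c(.3, .7))
  W + t(W)
}

# Independent-Bernoulli binary matrix (null network data).
null_binary <- function(n, p = 10, prob = 0.4, seed = 1) {
  set.seed(seed)
  binary_symptoms(matrix(rbinom(n * p, 1, prob), n, p))
}

# Fast estimator settings for resampling-heavy tests: a shorter lasso path
# and looser coordinate-descent threshold, which leave EBIC selection at
# these sample sizes essentially unchanged.
fast_ising <- function(m) {
  fit_ising(m, n_lambda = 30, lambda_min_ratio = 0.05, thresh = 1e-7)
}
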