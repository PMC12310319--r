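test_that("bootstrap of a constant estimator gives zero-width intervals", {
  m <- null_binary(100, p = 4, seed = 71)
  W <- random_weights(4, seed = 72)
  const_est <- function(mm) ising_network(W, thresholds = rep(0, 4),
                                          item_labels = colnames(mm))
  bt <- bootstrap_edges(m, const_est, B = 25, seed = 1)
  expect_equal(bt$edges$ci_lower, bt$edges$observed)
  expect_equal(bt$edges$ci_upper, bt$edges$observed)
  expect_true(all(!bt$diff_significant[W[upper.tri(W)] == 0,
                                       W[upper.tri(W)] == 0]))
})

test_that("bootstrap is bit-identical under the same seed", {
  params <- two_wave_preset()
  m <- sample_ising_gibbs(params$wave1, 600, burn_in = 200, seed = 73)
  b1 <- bootstrap_edges(m, fast_ising, B = 10, seed = 5)
  b2 <- bootstrap_edges(m, fast_ising, B = 10, seed = 5)
  expect_identical(b1$samples, b2$samples)
  b3 <- bootstrap_edges(m, fast_ising, B = 10, seed = 6)
  expect_false(identical(b1$samples, b3$samples))
})

test_that("true strong edges get bootstrap intervals excluding zero", {
  params <- two_wave_preset()
  m <- sample_ising_gibbs(params$wave1, 2000, burn_in = 300, seed = 74)
  bt <- bootstrap_edges(m, fast_ising, B = 60, seed = 2)
  truth <- params$wave1$weights[upper.tri(params$wave1$weights)] != 0
  covered <- bt$edges$excludes_zero[truth]
  expect_gte(mean(covered), 0.9)
})

test_that("bootstrap CI covers a strong known edge at near-nominal rate", {
  # two-node model with true logistic interaction 1.0; the nodewise
  # estimate of W12 should fall inside its own bootstrap CI ~95% of the time
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  params <- ising_params(W, c(-0.5, -0.5))
  hits <- 0L
  n_sim <- 30
  est2 <- function(mm) fit_ising(mm, n_lambda = 30, lambda_min_ratio = 0.05,
                                 thresh = 1e-7)
  for (s in seq_len(n_sim)) {
    m <- sample_ising_gibbs(params, 1500, burn_in = 100, seed = 300 + s)
    bt <- bootstrap_edges(m, est2, B = 120, seed = s)
    if (bt$edges$ci_lower[1] <= 1 && 1 <= bt$edges$ci_upper[1]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("a row-independent centrality gives the maximal CS coefficient", {
  m <- null_binary(200, p = 4, seed = 75)
  W <- random_weights(4, seed = 76)
  const_est <- function(mm) ising_network(W, thresholds = rep(0, 4),
                                          item_labels = colnames(mm))
  cs <- cs_coefficient(m, const_est, B = 15, seed = 3,
                       grid = seq(0.25, 0.75, by = 0.25))
  expect_equal(cs$cs, 0.75)
})

test_that("CS drops to nothing on pure-noise data", {
  m <- null_binary(200, p = 10, prob = 0.4, seed = 77)
  cs <- cs_coefficient(m, fast_ising, B = 20, seed = 4,
                       grid = seq(0.25, 0.75, by = 0.25))
  expect_lte(cs$cs, 0.25)
})

test_that("CS is monotone non-increasing in threshold and confidence", {
  params <- two_wave_preset()
  m <- sample_ising_gibbs(params$wave1, 1500, burn_in = 300, seed = 78)
  grid <- seq(0.25, 0.75, by = 0.25)
  base <- cs_coefficient(m, fast_ising, B = 15, seed = 5, grid = grid)
  stricter_r <- cs_coefficient(m, fast_ising, B = 15, seed = 5, grid = grid,
                               threshold_r = 0.95)
  stricter_c <- cs_coefficient(m, fast_ising, B = 15, seed = 5, grid = grid,
                               confidence = 1)
  expect_lte(stricter_r$cs, base$cs)
  expect_lte(stricter_c$cs, base$cs)
})

test_that("subsamples smaller than p are skipped with a warning", {
  m <- null_binary(13, p = 10, seed = 79)
  expect_warning(
    cs <- cs_coefficient(m, fast_ising, B = 2, seed = 6,
                         grid = c(0.05, 0.75)),
    "skipped")
})

test_that("centrality difference test separates a star centre from leaves", {
  params <- two_wave_preset()
  m <- sample_ising_gibbs(params$wave1, 3000, burn_in = 300, seed = 80)
  bt <- bootstrap_centrality_diff(m, fast_ising, B = 60, seed = 7)
  # duplicate columns cannot differ: compare an item against itself via the
  # observed symmetric indicator matrix
  expect_true(isSymmetric(bt$diff_significant))
  # the strongest and weakest nodes should separate at this n
  s <- node_strength_vector(fast_ising(m))
  hi <- which.max(s); lo <- which.min(s)
  expect_true(bt$diff_significant[hi, lo])
  # determinism
  bt2 <- bootstrap_centrality_diff(m, fast_ising, B = 60, seed = 7)
  expect_identical(bt$samples, bt2$samples)
})
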