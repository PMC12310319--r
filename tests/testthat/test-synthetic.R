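test_that("exact Ising pmf matches closed forms on two nodes", {
  # independence: uniform over the four states
  p0 <- ising_pmf_exact(ising_params(matrix(0, 2, 2), c(0, 0)))
  expect_equal(p0$prob, rep(0.25, 4))

  # W12 = ln 3: states 00,10,01 weight 1 each, state 11 weight 3
  W <- matrix(c(0, log(3), log(3), 0), 2, 2)
  p1 <- ising_pmf_exact(ising_params(W, c(0, 0)))
  both <- which(rowSums(p1$states) == 2)
  expect_equal(p1$prob[both], 0.5)

  # normalisation holds for arbitrary parameters
  pr <- ising_pmf_exact(toy_ising4())
  expect_equal(sum(pr$prob), 1)
  expect_true(all(pr$prob > 0))
})

test_that("Gibbs sampler is seeded, reproducible, and unbiased under the null", {
  flat <- ising_params(matrix(0, 4, 4), rep(0, 4))
  a <- sample_ising_gibbs(flat, 500, burn_in = 50, seed = 99)
  b <- sample_ising_gibbs(flat, 500, burn_in = 50, seed = 99)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a),
                         unclass(sample_ising_gibbs(flat, 500, burn_in = 50,
                                                    seed = 100))))

  big <- sample_ising_gibbs(flat, 10000, burn_in = 100, seed = 1)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(colMeans(big) - 0.5) < 3 * se))
})

test_that("Gibbs margins match exact enumeration on a 4-node model", {
  params <- toy_ising4()
  pm <- ising_pmf_exact(params)
  draws <- sample_ising_gibbs(params, 20000, burn_in = 200, seed = 5)
  marg_exact <- drop(crossprod(pm$states, pm$prob))
  expect_true(max(abs(colMeans(draws) - marg_exact)) < 0.02)
  # pairwise co-endorsement margins
  co_exact <- t(pm$states) %*% (pm$states * pm$prob)
  co_emp <- crossprod(unclass(draws)) / nrow(draws)
  expect_true(max(abs(co_exact - co_emp)) < 0.02)
})

test_that("two-wave generator honours the conditional logistic model", {
  p <- 4
  flat <- ising_params(matrix(0, p, p), rep(0, p))
  # pure autoregression: diag 2, intercept -1
  params <- two_wave_params(flat, diag(2, p), rep(-1, p))
  dat <- sample_two_wave(params, 10000, seed = 3, burn_in = 100)
  x1 <- unclass(dat$wave1); x2 <- unclass(dat$wave2)
  p_given1 <- colSums(x2 * x1) / colSums(x1)
  p_given0 <- colSums(x2 * (1 - x1)) / colSums(1 - x1)
  expect_true(all(abs(p_given1 - plogis(1)) < 0.03))
  expect_true(all(abs(p_given0 - plogis(-1)) < 0.03))

  # no cross-lagged effects: waves uncorrelated, wave-2 rates 1/2
  null_p <- two_wave_params(flat, matrix(0, p, p), rep(0, p))
  nd <- sample_two_wave(null_p, 10000, seed = 4, burn_in = 100)
  expect_true(all(abs(colMeans(nd$wave2) - 0.5) < 0.02))
  expect_true(all(abs(diag(cor(unclass(nd$wave1),
                               unclass(nd$wave2)))) < 0.05))

  # reproducibility
  d2 <- sample_two_wave(params, 100, seed = 3, burn_in = 100)
  d3 <- sample_two_wave(params, 100, seed = 3, burn_in = 100)
  expect_identical(unclass(d2$wave2), unclass(d3$wave2))
})

test_that("contemporaneous wave-2 couplings induce residual dependence", {
  p <- 4
  flat <- ising_params(matrix(0, p, p), rep(0, p))
  params <- two_wave_params(flat, matrix(0, p, p), rep(0, p))
  W2 <- matrix(0, p, p)
  W2[1, 2] <- W2[2, 1] <- 1.5
  dat <- sample_two_wave(params, 5000, seed = 9, burn_in = 200,
                         wave2_weights = W2)
  x2 <- unclass(dat$wave2)
  # with no cross-lagged effects the wave-2 association is purely
  # contemporaneous: items 1-2 correlate, 3-4 do not
  expect_gt(cor(x2[, 1], x2[, 2]), 0.2)
  expect_lt(abs(cor(x2[, 3], x2[, 4])), 0.05)
  # deterministic under seed
  dat2 <- sample_two_wave(params, 100, seed = 9, burn_in = 200,
                          wave2_weights = W2)
  dat3 <- sample_two_wave(params, 100, seed = 9, burn_in = 200,
                          wave2_weights = W2)
  expect_identical(unclass(dat2$wave2), unclass(dat3$wave2))
})

test_that("wave-2 items are conditionally independent given wave 1", {
  params <- two_wave_preset()
  dat <- sample_two_wave(params, 20000, seed = 8, burn_in = 300)
  x1 <- unclass(dat$wave1); x2 <- unclass(dat$wave2)
  # residualise each wave-2 item on the full wave-1 state; residual
  # correlations across items should vanish at large n
  res <- apply(x2, 2, function(y) residuals(lm(y ~ x1)))
  rc <- cor(res)
  expect_true(max(abs(rc[upper.tri(rc)])) < 0.04)
})

test_that("preset reproduces its calibration targets and driver design", {
  params <- two_wave_preset()
  expect_identical(attr(params, "driver"), 8L)
  # exact endorsement rates in the calibrated band
  pm <- ising_pmf_exact(params$wave1)
  marg <- drop(crossprod(pm$states, pm$prob))
  expect_true(all(marg > 0.15 & marg < 0.72))
  # simulated rates agree
  draws <- sample_ising_gibbs(params$wave1, 20000, burn_in = 300, seed = 2)
  expect_true(all(colMeans(draws) > 0.15 & colMeans(draws) < 0.72))
  # structure: 12 undirected edges, 5 cross-lagged effects, driver has the
  # largest true out-EI by construction
  expect_equal(sum(params$wave1$weights[upper.tri(params$wave1$weights)] != 0),
               12)
  B <- params$crosslag; diag(B) <- 0
  expect_equal(sum(B != 0), 5)
  expect_equal(which.max(rowSums(B)), attr(params, "driver"),
               ignore_attr = TRUE)
  # deterministic under the same seed
  expect_identical(two_wave_preset(seed = 2020)$crosslag, params$crosslag)
})
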