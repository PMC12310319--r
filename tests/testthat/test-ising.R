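test_that("EBIC formula matches hand arithmetic and reduces to BIC", {
  expect_equal(ebic(-100, 2, 1000, 9, gamma = 0.5),
               200 + 2 * log(1000) + 2 * log(9))
  expect_equal(ebic(-50, 0, 500, 9, gamma = 0.5), 100)
  expect_equal(ebic(-100, 3, 1000, 9, gamma = 0),
               -2 * (-100) + 3 * log(1000))
})

test_that("the lasso path starts at the null model with the marginal intercept", {
  m <- sample_ising_gibbs(toy_ising4(), 800, burn_in = 100, seed = 21)
  x <- unclass(m)
  path <- nodewise_lasso_path(x[, 1], x[, -1])
  expect_true(all(path$beta[, 1] == 0))
  expect_equal(path$intercepts[1], qlogis(mean(x[, 1])), tolerance = 1e-6)
  expect_true(all(diff(path$lambda) < 0))
  expect_true(all(is.finite(path$ebic)))
})

test_that("a strong single predictor is recovered near its true log-odds", {
  set.seed(33)
  n <- 5000
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)  # pure noise
  y <- rbinom(n, 1, plogis(-1 + 2 * x1))
  path <- nodewise_lasso_path(y, cbind(x1, x2))
  beta_small_lambda <- path$beta[1, length(path$lambda)]
  unpen <- coef(glm(y ~ x1 + x2, family = binomial()))["x1"]
  expect_lt(abs(beta_small_lambda - 2), 0.25)
  expect_lt(abs(beta_small_lambda - unpen), 0.1)
})

test_that("path solutions satisfy the lasso KKT optimality conditions", {
  m <- sample_ising_gibbs(toy_ising4(), 600, burn_in = 100, seed = 22)
  x <- unclass(m)
  y <- x[, 2]
  X <- x[, -2]
  path <- nodewise_lasso_path(y, X, thresh = 1e-12)
  n <- length(y)
  for (i in seq_along(path$lambda)) {
    eta <- path$intercepts[i] + drop(X %*% path$beta[, i])
    score <- drop(crossprod(X, y - plogis(eta))) / n
    lam <- path$lambda[i]
    active <- path$beta[, i] != 0
    expect_true(all(abs(score[!active]) <= lam + 1e-4))
    if (any(active)) {
      expect_true(all(abs(score[active] -
                            lam * sign(path$beta[active, i])) < 1e-4))
    }
  }
})

test_that("estimated networks are symmetric, zero-diagonal, row-order invariant", {
  m <- sample_ising_gibbs(toy_ising4(), 1000, burn_in = 100, seed = 23)
  net <- fit_ising(m)
  expect_equal(net$weights, t(net$weights))
  expect_equal(unname(diag(net$weights)), rep(0, 4))
  perm <- unclass(m)[sample(nrow(m)), , drop = FALSE]
  net2 <- fit_ising(binary_symptoms(perm))
  expect_equal(net$weights, net2$weights)
})

test_that("AND-rule network is never denser than the OR-rule network", {
  params <- two_wave_preset()
  m <- sample_ising_gibbs(params$wave1, 1500, burn_in = 300, seed = 24)
  a <- fit_ising(m, rule = "and")
  o <- fit_ising(m, rule = "or")
  ea <- a$weights[upper.tri(a$weights)] != 0
  eo <- o$weights[upper.tri(o$weights)] != 0
  expect_true(all(!ea | eo))  # every AND edge is an OR edge
})

test_that("stacking the dataset twice leaves the selected edge set stable", {
  # duplicating rows scales the likelihood uniformly; EBIC penalties change
  # only through log(2n), so at sample sizes where selection has a clear
  # margin the active set must not move (weights match exactly whenever the
  # same grid point stays selected)
  params <- toy_ising4()
  for (s in c(21, 24, 25)) {
    m <- sample_ising_gibbs(params, 3000, burn_in = 200, seed = s)
    x <- unclass(m)
    net1 <- fit_ising(m)
    net2 <- fit_ising(binary_symptoms(rbind(x, x)))
    expect_equal(net1$weights != 0, net2$weights != 0)
  }
  m <- sample_ising_gibbs(params, 3000, burn_in = 200, seed = 21)
  x <- unclass(m)
  expect_lt(max(abs(fit_ising(m)$weights -
                      fit_ising(binary_symptoms(rbind(x, x)))$weights)),
            1e-6)
})

test_that("recovery of the true edge set improves with sample size", {
  params <- two_wave_preset()
  truth <- params$wave1$weights[upper.tri(params$wave1$weights)] != 0
  sens <- vapply(c(500, 2000, 8000), function(n) {
    m <- sample_ising_gibbs(params$wave1, n, burn_in = 300, seed = 26)
    est <- fit_ising(m)$weights
    found <- est[upper.tri(est)] != 0
    sum(found & truth) / sum(truth)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gte(sens[3], 0.9)
})

test_that("a constant column isolates its node with a warning", {
  m <- null_binary(300, p = 5, seed = 27)
  x <- unclass(m)
  x[, 3] <- 1L
  expect_warning(net <- fit_ising(binary_symptoms(x)), "constant")
  expect_true(all(net$weights[3, ] == 0))
  expect_true(is.finite(net$thresholds[3]))
})

test_that("global strength sums absolute unique edge weights", {
  expect_equal(global_strength(matrix(0, 10, 10)), 0)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1.48
  expect_equal(global_strength(W), 1.48)
  W[1, 3] <- W[3, 1] <- -0.25
  W[2, 3] <- W[3, 2] <- 1.0
  W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(global_strength(W), 1.75)
})
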