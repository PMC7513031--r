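test_that("a single-particle update reduces to the Kalman analysis", {
  pr <- mixture_prior(matrix(0.5), NULL, matrix(1), matrix(2))
  obs <- linear_mixed_obs(v = 1.3, Gbar = matrix(0.7), Gprime = matrix(1.5),
                          r_theta = matrix(0.4))
  po <- analysis_update(pr, obs)
  S <- 1.5 * 2 * 1.5 + 0.4
  K <- 2 * 1.5 / S
  expect_equal(po$weights, 1)
  expect_equal(po$cond_means[1, 1], 1 + K * (1.3 - 0.7 * 0.5 - 1.5 * 1))
  expect_equal(po$cond_covs[[1]][1, 1], (1 - K * 1.5) * 2)
})

test_that("with no small-scale footprint only the weights move", {
  # Gprime = 0 is rank deficient for M = 1, so observe 2 components with a
  # zero block acting on the small scales via a large-scale-only operator:
  # here use Gprime with full row rank but zero gain through R' = 0
  pr <- mixture_prior(matrix(c(-1, 0, 2)), NULL,
                      matrix(c(0.5, 1, -0.5)),
                      list(matrix(0), matrix(0), matrix(0)))
  obs <- linear_mixed_obs(v = 0.4, Gbar = matrix(1), Gprime = matrix(1),
                          r_theta = matrix(0.25))
  po <- analysis_update(pr, obs)
  expect_equal(po$cond_means, pr$cond_means)
  lik <- stats::dnorm(0.4, pr$particles[, 1] + pr$cond_means[, 1], 0.5)
  expect_equal(po$weights, lik / sum(lik))
})

test_that("closed-form marginal likelihoods match the quadrature oracle", {
  pr <- mixture_prior(matrix(c(-1, 0, 1)), c(0.2, 0.3, 0.5),
                      matrix(c(0.5, 1, -0.5)),
                      list(matrix(1), matrix(2), matrix(0.5)))
  obs <- linear_mixed_obs(v = 1.3, Gbar = matrix(0.7), Gprime = matrix(1.5),
                          r_theta = matrix(0.4))
  Ij <- vapply(1:3, function(j)
    stats::integrate(function(up)
      stats::dnorm(1.3, 0.7 * pr$particles[j, 1] + 1.5 * up, sqrt(0.4)) *
        stats::dnorm(up, pr$cond_means[j, 1],
                     sqrt(pr$cond_covs[[j]][1, 1])),
      -30, 30)$value, numeric(1))
  po <- analysis_update(pr, obs)
  w_oracle <- pr$weights * Ij / sum(pr$weights * Ij)
  expect_equal(po$weights, w_oracle, tolerance = 1e-8)
  expect_equal(sum(po$weights), 1)
  for (S in po$cond_covs)
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
})

test_that("the mixture posterior approaches the exact Kalman posterior as Q grows", {
  # linear-Gaussian toy: ubar ~ N(0, 1) (particles), u' | ubar ~ N(ubar, 0.5)
  # observation v = ubar + u' + noise; exact joint posterior is Gaussian
  set.seed(51)
  v_obs <- 1.2; r <- 0.3
  # exact posterior moments of u' from the 2-d Gaussian model
  # cov(ubar, u') setup: ubar ~ N(0,1), u' = ubar + e, e ~ N(0, 0.5)
  C <- matrix(c(1, 1, 1, 1.5), 2)       # cov of (ubar, u')
  H <- matrix(c(1, 1), 1)               # v = ubar + u' + noise
  S <- H %*% C %*% t(H) + r
  Kg <- C %*% t(H) %*% solve(S)
  post_mean <- drop(Kg %*% v_obs)[2]
  post_cov <- (C - Kg %*% H %*% C)[2, 2]
  errs <- vapply(c(50, 400, 3000), function(Q) {
    ub <- stats::rnorm(Q)
    pr <- mixture_prior(matrix(ub), NULL, matrix(ub),
                        rep(list(matrix(0.5)), Q))
    po <- analysis_update(pr, linear_mixed_obs(v_obs, matrix(1), matrix(1),
                                               matrix(r)))
    mm <- mixture_prior_moments(po)
    abs(mm$mean - post_mean) + abs(mm$cov[1, 1] - post_cov)
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1] + 0.02)
})

test_that("resampling triggers on low effective sample size and is reproducible", {
  pr <- mixture_prior(matrix(1:4), rep(0.25, 4), matrix(rep(0, 4)),
                      rep(list(matrix(1)), 4))
  expect_identical(resample_particles(pr, 0.5), pr)   # uniform: unchanged
  skew <- mixture_prior(matrix(1:4), c(1 - 3e-9, 1e-9, 1e-9, 1e-9),
                        matrix(rep(0, 4)), rep(list(matrix(1)), 4))
  rs <- resample_particles(skew, 0.5, seed = 3)
  expect_true(all(rs$particles == 1))                 # all copies of the heavy one
  expect_equal(rs$weights, rep(0.25, 4))
  rs2 <- resample_particles(skew, 0.5, seed = 3)
  expect_identical(rs, rs2)
})

test_that("rank-deficient observation operators are refused; underflow falls back", {
  pr <- mixture_prior(matrix(c(0, 1)), NULL, matrix(0, 2, 2),
                      rep(list(diag(1, 2)), 2))
  obs <- linear_mixed_obs(v = c(0, 0), Gbar = matrix(0, 2, 1),
                          Gprime = matrix(c(1, 1, 0, 0), 2, 2),
                          r_theta = diag(0.1, 2))
  expect_error(analysis_update(pr, obs), "rank deficient")
  pr1 <- mixture_prior(matrix(c(0, 1)), NULL, matrix(c(0, 0)),
                       rep(list(matrix(1e-300)), 2))
  obs1 <- linear_mixed_obs(v = 1e8, Gbar = matrix(1), Gprime = matrix(1),
                           r_theta = matrix(1e-300))
  expect_warning(po <- analysis_update(pr1, obs1), "underflow")
  expect_equal(po$weights, c(0.5, 0.5))
})
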