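test_that("direct augmentation matches the conjugate-Gaussian closed form", {
  # duI = lambda dt + sigma dW with lambda* = 2: the posterior for lambda is
  # Gaussian with precision 1/C0 + T/sigma^2 and mean
  # (m0/C0 + (u_T - u_0)/sigma^2) / precision
  sigma <- 0.5; lam <- 2
  pm <- constant_drift_param_model(sigma)
  spec <- cg_model(1, 0,
                   A0 = function(t, uI) lam,
                   A1 = function(t, uI) matrix(0, 1, 0),
                   a0 = function(t, uI) numeric(0),
                   a1 = function(t, uI) matrix(0, 0, 0),
                   SigmaI = function(t, uI) sigma,
                   SigmaII = function(t, uI) numeric(0))
  tr <- simulate_sde(spec, 0, T = 10, dt = 1e-3, seed = 17)
  m0 <- 0.5; C0 <- 2
  est <- estimate_direct(pm, tr, prior_mean = m0, prior_cov = matrix(C0))
  prec <- 1 / C0 + 10 / sigma^2
  m_post <- (m0 / C0 + (tr$uI[nrow(tr$uI), 1] - tr$uI[1, 1]) / sigma^2) / prec
  nt <- length(est$t)
  expect_equal(est$mean_path[nt, 1], m_post, tolerance = 1e-3)
  expect_equal(est$var_path[nt, 1], 1 / prec, tolerance = 1e-3)
})

test_that("zero prior covariance pins the direct estimate at the prior mean", {
  pm <- constant_drift_param_model(0.5)
  spec <- build_model("ou")
  tr <- simulate_sde(spec, 1, T = 5, dt = 0.005, seed = 2)
  est <- estimate_direct(pm, tr, prior_mean = 1.7, prior_cov = matrix(0))
  expect_true(all(est$mean_path == 1.7))
  expect_true(all(est$var_path == 0))
})

test_that("direct estimation of the Lorenz 63 parameters converges with shrinking variance", {
  tr <- l63_obs_traj(noise = 5, T = 25, dt = 0.002, seed = 19)
  pm <- l63_param_model(sigma_obs = rep(5, 3))
  est <- estimate_direct(pm, tr, prior_mean = rep(0, 3),
                         prior_cov = diag(1, 3))
  truth <- c(10, 28, 8 / 3)
  expect_lt(max(abs(est$point_estimate - truth) / truth), 0.15)
  # posterior variance is monotone non-increasing (no positive source term)
  for (j in 1:3) expect_true(all(diff(est$var_path[, j]) <= 1e-12))
  nt <- nrow(est$var_path)
  expect_lt(max(est$var_path[nt, ]), 0.1)
})

test_that("larger observation noise slows direct-scheme convergence", {
  # small observation noise makes the covariance contraction fast relative to
  # the step, so a finer grid and a modest prior keep explicit Euler stable
  t_half <- vapply(c(1, 5, 15), function(noise) {
    mean(vapply(1:2, function(s) {
      tr <- l63_obs_traj(noise, T = 10, dt = 5e-4, seed = 100 + s)
      est <- estimate_direct(l63_param_model(rep(noise, 3)), tr,
                             prior_mean = rep(0, 3),
                             prior_cov = diag(0.25, 3))
      v <- rowSums(est$var_path)
      est$t[which(v <= v[1] / 2)[1]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(t_half) > 0))
})

test_that("an infinitely stiff OU prior pins the stochastic-parameterized estimate", {
  tr <- l63_obs_traj(noise = 5, T = 5, dt = 0.002, seed = 23)
  pm <- l63_param_model(rep(5, 3))
  hat <- c(12, 33.6, 3.2)
  est <- estimate_stochastic_param(pm, tr, ou_d = 500, ou_mean = hat,
                                   ou_sigma = rep(1e-6, 3),
                                   init_mean = hat, init_cov = diag(0, 3))
  expect_equal(est$point_estimate, hat, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(estimate_stochastic_param(pm, tr, ou_d = -1, ou_mean = hat,
                                         ou_sigma = rep(1, 3)), "ou_d")
})

test_that("stochastic-parameterized estimates are robust to the prior damping", {
  tr <- l63_obs_traj(noise = 15, T = 30, dt = 0.002, seed = 29)
  pm <- l63_param_model(rep(15, 3))
  truth <- c(10, 28, 8 / 3)
  ests <- lapply(c(0.25, 0.5, 0.75), function(d)
    estimate_stochastic_param(pm, tr, ou_d = d,
                              ou_mean = c(12, 33.6, 3.2),
                              ou_sigma = c(2, 5.6, 1.6 / 3),
                              window = c(10, 30))$point_estimate)
  for (e in ests) expect_lt(max(abs(e - truth) / truth), 0.25)
})

test_that("stochastic-parameterized point estimates disperse little across seeds", {
  pm <- l63_param_model(rep(15, 3))
  truth <- c(10, 28, 8 / 3)
  ests <- vapply(1:4, function(s) {
    tr <- l63_obs_traj(noise = 15, T = 30, dt = 0.002, seed = 300 + s)
    estimate_stochastic_param(pm, tr, ou_d = 0.5,
                              ou_mean = c(12, 33.6, 3.2),
                              ou_sigma = c(2, 5.6, 1.6 / 3),
                              window = c(10, 30))$point_estimate
  }, numeric(3))
  disp <- apply(ests, 1, stats::sd)
  expect_true(all(disp / truth < 0.1))
})

test_that("the fixed-point scheme is self-consistent when started at the truth", {
  spec <- build_model("spekf_m")
  tr <- simulate_sde(spec, c(2, 1), T = 400, dt = 0.005, seed = 31)
  est <- suppressWarnings(
    estimate_unresolved_fixed_point(tr, init = c(0.5, 0.5, 1), max_iter = 1))
  first <- est$iterates[2, ]
  expect_equal(first[["gamma_hat"]], 1, tolerance = 0.15)
  expect_equal(first[["sigma_gamma"]]^2 / (2 * first[["d_gamma"]]), 0.25,
               tolerance = 0.12)
})

test_that("longer records tighten the fixed-point implied variance", {
  iv <- vapply(c(250, 1000), function(T) {
    tr <- simulate_sde(build_model("spekf_m"), c(2, 1), T = T, dt = 0.01,
                       seed = 201)
    est <- suppressWarnings(
      estimate_unresolved_fixed_point(tr, init = c(0.1, 1, 2.5),
                                      max_iter = 6))
    est$point_estimate[1]^2 / (2 * est$point_estimate[2])
  }, numeric(1))
  expect_lt(abs(iv[2] - 0.25), abs(iv[1] - 0.25) + 0.05)
})
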