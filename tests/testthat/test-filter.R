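test_that("filter covariance converges to the algebraic Riccati root", {
  a <- 1; sI <- 0.5; sII <- 1
  spec <- linear_scalar_model(a, sI, sII)
  tr <- simulate_sde(spec, c(0, 1), T = 30, dt = 0.002, seed = 3)
  fp <- filter_posterior(spec, tr, init_mean = 0, init_cov = matrix(1))
  expect_equal(fp$cov[1, 1, length(fp$t)], riccati_root(a, sI, sII),
               tolerance = 1e-6)
})

test_that("a noiseless hidden process with exact init keeps zero covariance", {
  # SigmaII = 0, exact init: R = 0 is a fixed point and the mean solves the
  # hidden ODE driven by the observed path
  spec <- cg_model(1, 1,
                   A0 = function(t, uI) -uI,
                   A1 = function(t, uI) matrix(0, 1, 1),
                   a0 = function(t, uI) uI,
                   a1 = function(t, uI) matrix(-1, 1, 1),
                   SigmaI = function(t, uI) 0.3,
                   SigmaII = function(t, uI) 0)
  tr <- simulate_sde(spec, c(1, 0.5), T = 2, dt = 1e-3, seed = 2)
  fp <- filter_posterior(spec, tr, init_mean = 0.5, init_cov = matrix(0))
  expect_equal(max(abs(fp$cov)), 0)
  # forward-Euler ODE oracle for the hidden mean
  m <- 0.5
  for (n in seq_len(nrow(tr$uI) - 1)) m <- m + (tr$uI[n, 1] - m) * tr$dt
  expect_equal(fp$mean[nrow(fp$mean), 1], m)
})

test_that("Kalman-Bucy is the shared code path on linear models and refuses nonlinear ones", {
  spec <- linear_scalar_model()
  tr <- simulate_sde(spec, c(0, 1), T = 5, dt = 0.005, seed = 4)
  fp <- filter_posterior(spec, tr, init_mean = 0, init_cov = matrix(1))
  kb <- kalman_bucy(spec, tr, init_mean = 0, init_cov = matrix(1))
  expect_identical(kb$mean, fp$mean)
  expect_identical(kb$cov, fp$cov)
  expect_error(kalman_bucy(build_model("dyad"), tr),
               "not a linear")
})

test_that("with no information flow the posterior equals the prior moment ODE", {
  # A1 = 0: the observation carries no signal; posterior = unconditioned
  # Gaussian moments of the hidden OU process
  a <- 0.7; sII <- 0.8
  spec <- cg_model(1, 1,
                   A0 = function(t, uI) -uI,
                   A1 = function(t, uI) matrix(0, 1, 1),
                   a0 = function(t, uI) 0,
                   a1 = function(t, uI) matrix(-a, 1, 1),
                   SigmaI = function(t, uI) 0.5,
                   SigmaII = function(t, uI) sII)
  tr <- simulate_sde(spec, c(0, 2), T = 3, dt = 1e-3, seed = 6)
  fp <- filter_posterior(spec, tr, init_mean = 2, init_cov = matrix(0.3))
  tt <- max(tr$t)
  expect_equal(fp$mean[length(fp$t), 1], 2 * exp(-a * tt), tolerance = 1e-2)
  R_exact <- 0.3 * exp(-2 * a * tt) + sII^2 * (1 - exp(-2 * a * tt)) / (2 * a)
  expect_equal(fp$cov[1, 1, length(fp$t)], R_exact, tolerance = 1e-2)
})

test_that("blocked filtering agrees with the full filter on a small instance", {
  spec <- build_model("two_layer_l96", I = 4, J = 2)
  set.seed(11)
  u0 <- c(stats::rnorm(4), rep(0, 8))
  tr <- simulate_sde(spec, u0, T = 5, dt = 0.005, seed = 7)
  f_full <- filter_posterior(spec, tr, init_mean = rep(0, 8),
                             init_cov = diag(1, 8))
  f_blk <- filter_posterior_blocked(spec, tr, init_mean = rep(0, 8),
                                    init_cov_blocks = 1,
                                    check_condition = TRUE)
  nt <- length(tr$t)
  expect_lt(max(abs(f_full$mean - f_blk$mean)), 1e-8)
  expect_lt(max(abs(f_full$cov[, , nt] -
                      condgauss:::filter_cov_at(f_blk, nt))), 1e-8)
})

test_that("posterior covariance stays positive semi-definite along zoo paths", {
  for (nm in c("dyad", "fhn3d", "triad", "spekf")) {
    spec <- build_model(nm)
    u0 <- rep(0.5, spec$n_I + spec$n_II)
    tr <- simulate_sde(spec, u0, T = 2, dt = spec$default_dt, seed = 13)
    # modest initial spread: the fast FHN time scale makes the explicit
    # Euler covariance update overshoot for wide initializations
    fp <- filter_posterior(spec, tr, init_mean = rep(0, spec$n_II),
                           init_cov = diag(0.01, spec$n_II))
    idx <- round(seq(1, length(fp$t), length.out = 20))
    for (i in idx) {
      ev <- eigen(condgauss:::filter_cov_at(fp, i), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
    }
  }
})

test_that("singular observed noise errors unless regularization is enabled", {
  # degenerate second observed component that carries no hidden signal
  spec <- cg_model(2, 1,
                   A0 = function(t, uI) c(0, 0),
                   A1 = function(t, uI) matrix(c(1, 0), 2, 1),
                   a0 = function(t, uI) 0,
                   a1 = function(t, uI) matrix(-1, 1, 1),
                   SigmaI = function(t, uI) c(0.5, 0),
                   SigmaII = function(t, uI) 0.5)
  tr <- structure(list(t = seq(0, 1, by = 0.01),
                       uI = matrix(0.1, 101, 2), dt = 0.01, seed = 1,
                       n_clipped = 0L, model = "toy"),
                  class = "cg_trajectory")
  expect_error(filter_posterior(spec, tr, 0, matrix(1)),
               "rows: 2")
  expect_silent(filter_posterior(spec, tr, 0, matrix(1), regularize = TRUE))
})
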