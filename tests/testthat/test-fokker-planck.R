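test_that("plug-in bandwidth matches the Gaussian-reference value and scales affinely", {
  set.seed(21)
  x <- stats::rnorm(1e4)
  h <- kde_bandwidth(x)
  expect_equal(h, (4 / (3 * 1e4))^(1 / 5), tolerance = 0.15)
  expect_equal(kde_bandwidth(3 * x), 3 * h, tolerance = 1e-8)
  # heavy tails: the solve differs from the rule of thumb (non-degenerate fit)
  y <- stats::rt(5e3, df = 3)
  expect_gt(abs(kde_bandwidth(y) - stats::bw.nrd0(y)) / stats::bw.nrd0(y),
            0.01)
  expect_warning(kde_bandwidth(stats::rnorm(5)), "fewer than 8")
})

test_that("observed-marginal KDE recovers known densities", {
  set.seed(22)
  x <- stats::rnorm(500)
  mix <- observed_marginal(x)
  g <- seq(-4, 4, length.out = 401)
  ise <- condgauss:::trapz(g, (mixture_density(mix, g) - stats::dnorm(g))^2)
  # AMISE for a Gaussian kernel on N(0,1):
  # (5/4) R(K)^{4/5} R(f'')^{1/5} n^{-4/5} ~= 0.333 n^{-4/5}; slack x2
  bound <- 2 * 1.25 * (0.5 / sqrt(pi))^(4 / 5) *
    (3 / (8 * sqrt(pi)))^(1 / 5) * 500^(-4 / 5)
  expect_lt(ise, bound)
  # well-separated bimodal sample keeps two modes
  xb <- c(stats::rnorm(400, -2), stats::rnorm(400, 2))
  db <- mixture_density(observed_marginal(xb), seq(-5, 5, length.out = 501))
  n_modes <- sum(diff(sign(diff(db))) == -2)
  expect_equal(n_modes, 2)
  expect_warning(observed_marginal(rep(1, 20)), "degenerate|fewer")
  expect_error(observed_marginal(matrix(1, 1, 1)), "at least 2")
})

test_that("hidden marginal converges to the exact Gaussian Fokker-Planck solution", {
  a <- 1; sII <- 1
  spec <- linear_scalar_model(a, 0.5, sII)
  t_eval <- 1; u0 <- c(0, 1)
  m_ex <- exp(-a * t_eval)
  v_ex <- sII^2 * (1 - exp(-2 * a * t_eval)) / (2 * a)
  err <- vapply(c(10, 50, 250), function(L) {
    mean(vapply(1:3, function(s) {
      mom <- mixture_moments(hidden_marginal(spec, L, t_eval, u0, dt = 0.005,
                                             seed = s))
      abs(mom$mean - m_ex) + abs(mom$var - v_ex)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))      # error decreases with L
  expect_lt(err[3], 0.08)
  # L = 1 is a single Gaussian: that path's conditional law
  one <- hidden_marginal(spec, 1, t_eval, u0, dt = 0.005, seed = 1)
  expect_equal(one$L, 1L)
})

test_that("small scales of the conceptual turbulence model are negatively skewed", {
  spec <- build_model("conceptual_mod")
  u0 <- c(1, rep(0, 5))
  mix <- hidden_marginal(spec, 100, 15, u0, dt = 0.01, seed = 31)
  mom <- mixture_moments(mixture_marginal(mix, 1))
  # Monte Carlo oracle: ergodic long run of the same system
  long <- simulate_sde(spec, u0, T = 1000, dt = 0.01, seed = 32)
  v1 <- long$uII[-(1:5000), 1]
  sk_mc <- mean((v1 - mean(v1))^3) / stats::sd(v1)^3
  expect_lt(sk_mc, 0)                  # the -gamma u^2 feedback skews left
  expect_lt(mom$skewness, 0)
})

test_that("hybrid joint marginalizes exactly and normalizes", {
  spec <- build_model("fhn3d")
  u0 <- c(-2, 0.5, 1)
  hj <- hybrid_joint(spec, 50, 0.5, u0, seed = 4)
  st <- condgauss:::cg_ensemble_state(spec, 50, 0.5, u0, spec$default_dt, 4,
                                      0, FALSE)
  g <- seq(-3, 3, length.out = 101)
  # over the hidden block: recovers the kernel density of the observed state
  obs <- observed_marginal(st$uI_ends)
  expect_equal(mixture_density(mixture_marginal(hj, 1), g),
               mixture_density(obs, g))
  # over the observed block: recovers the conditional Gaussian mixture
  hid <- gaussian_mixture(st$hid_means, st$hid_covs)
  gg <- as.matrix(expand.grid(g, seq(0, 2, length.out = 21)))
  expect_equal(mixture_density(mixture_marginal(hj, 2:3), gg),
               mixture_density(hid, gg))
  expect_equal(mixture_normalization(mixture_marginal(hj, 1)), 1,
               tolerance = 1e-3)
})

test_that("hybrid-solver marginals of the single-site FHN model match Monte Carlo", {
  spec <- build_model("fhn3d")
  u0 <- c(-2, 0.5, 1)
  # evaluated before the first firing events: beyond that, the burst tail
  # carries sub-permille mass that a desk-scale Monte Carlo truth cannot
  # itself resolve, and the tail-sensitive relative entropy would compare
  # two unresolved estimates
  t_eval <- 0.3
  hj <- hybrid_joint(spec, 200, t_eval, u0, dt = 0.002, seed = 61)
  mc <- ensemble_simulate(spec, u0, 5000, T = t_eval, dt = 0.002, seed = 62)
  nt <- length(mc[[1]]$t)
  ends <- t(vapply(mc, function(tr) c(tr$uI[nt, ], tr$uII[nt, ]), numeric(3)))
  for (j in 1:3) {
    s <- ends[, j]
    g <- seq(min(s) - 0.5, max(s) + 0.5, length.out = 512)
    p_mc <- mixture_density(observed_marginal(s), g)
    p_hj <- mixture_density(mixture_marginal(hj, j), g)
    expect_lt(relative_entropy(p_mc, p_hj, g), 0.1)
  }
})

test_that("mixture moments match closed forms and Monte Carlo", {
  mix <- gaussian_mixture(matrix(c(-1, 2)), matrix(c(0.5, 2)),
                          weights = c(0.3, 0.7))
  set.seed(23)
  comp <- sample(1:2, 1e6, replace = TRUE, prob = c(0.3, 0.7))
  xs <- stats::rnorm(1e6, c(-1, 2)[comp], sqrt(c(0.5, 2))[comp])
  mom <- mixture_moments(mix)
  expect_equal(mom$mean, mean(xs), tolerance = 0.01)
  expect_equal(mom$var, stats::var(xs), tolerance = 0.01)
  z <- (xs - mean(xs)) / stats::sd(xs)
  expect_equal(mom$skewness, mean(z^3), tolerance = 0.02)
  expect_equal(mom$kurtosis, mean(z^4), tolerance = 0.05)
  # single standard Gaussian: skewness 0, kurtosis 3
  g1 <- mixture_moments(gaussian_mixture(matrix(0), matrix(1)))
  expect_equal(g1$skewness, 0)
  expect_equal(g1$kurtosis, 3)
  expect_equal(mixture_normalization(mix), 1, tolerance = 1e-3)
})

test_that("statistical symmetry pools site Gaussians; asymmetric models refuse", {
  fhn <- build_model("fhn_lattice", N = 2)
  # K = 2 toy: the mixture is the average of the two site Gaussians
  mix <- symmetry_augment(fhn, site_means = c(-1, 1), site_vars = c(0.5, 0.5))
  g <- seq(-4, 4, length.out = 201)
  expect_equal(mixture_density(mix, g),
               0.5 * (stats::dnorm(g, -1, sqrt(0.5)) +
                        stats::dnorm(g, 1, sqrt(0.5))))
  # shifted-index 2-d pairing with cyclic wrap
  j2 <- symmetry_augment(fhn, site_means = c(-1, 1), site_vars = c(0.4, 0.6),
                         offset = 1)
  expect_equal(j2$means, cbind(site_means = c(-1, 1), c(1, -1)),
               ignore_attr = TRUE)
  expect_equal(j2$covs, cbind(site_vars = c(0.4, 0.6), c(0.6, 0.4)),
               ignore_attr = TRUE)
  l96 <- build_model("two_layer_l96", I = 4, J = 2)   # inhomogeneous
  expect_error(symmetry_augment(l96, c(0, 1, 2, 3), rep(1, 4)),
               "not flagged statistically symmetric")
})

test_that("single-run symmetry prediction of the FHN lattice matches pooled Monte Carlo", {
  # one simulation of an N-site homogeneous lattice provides N samples
  # (effective ensemble K x L with L = 1); its marginals agree with a pooled
  # multi-run Monte Carlo truth in relative entropy
  r <- run_experiment("fhn_prediction",
                      overrides = list(N = 100, n_mc_runs = 20),
                      out_dir = tempfile("fhn"), seed = 2)
  expect_lt(max(r$relative_entropy$relative_entropy), 0.1)
})
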