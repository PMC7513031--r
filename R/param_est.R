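# Parameter estimation built on the conditional Gaussian filter.  Unknown
# parameters that enter the observed drift affinely are appended to the
# hidden subspace; the closed-form filter then delivers their posterior.

#' Parameter-augmented model
#'
#' Describes an observed process whose drift is affine in the unknown
#' parameter vector `Lambda`:
#' `duI = [A0(t, uI) + A1_lambda(t, uI) Lambda] dt + SigmaI dWI`.
#' The estimation schemes attach their own hidden dynamics for `Lambda`
#' (trivial `dLambda = 0` for the direct scheme, an Ornstein--Uhlenbeck
#' prior for the stochastic-parameterized scheme).
#'
#' @param n_I observed dimension.
#' @param n_par number of unknown parameters.
#' @param A0 function `(t, uI)` -> known part of the observed drift.
#' @param A1_lambda function `(t, uI)` -> `n_I x n_par` matrix multiplying
#'   `Lambda`.
#' @param SigmaI observed diffusion, function `(t, uI)`.
#' @param par_names parameter labels.
#' @return a `cg_param_model`.
#' @export
param_model <- function(n_I, n_par, A0, A1_lambda, SigmaI,
                        par_names = paste0("lambda", seq_len(n_par))) {
  structure(list(n_I = n_I, n_par = n_par, A0 = A0, A1_lambda = A1_lambda,
                 SigmaI = SigmaI, par_names = par_names),
            class = "cg_param_model")
}

#' Parameter-augmented model for the noisy Lorenz 63 system
#'
#' The three parameters (sigma, rho, beta) enter the drift of `(x, y, z)`
#' affinely, so they can be estimated from the observed trajectory alone.
#'
#' @param sigma_obs observation noise standard deviations (length 3 or
#'   scalar).
#' @export
l63_param_model <- function(sigma_obs = c(5, 5, 5)) {
  if (length(sigma_obs) == 1) sigma_obs <- rep(sigma_obs, 3)
  param_model(
    n_I = 3, n_par = 3,
    A0 = function(t, uI) c(0, -uI[1] * uI[3] - uI[2], uI[1] * uI[2]),
    A1_lambda = function(t, uI) matrix(c(
      uI[2] - uI[1], 0, 0,
      0, uI[1], 0,
      0, 0, -uI[3]), 3, 3),
    SigmaI = function(t, uI) sigma_obs,
    par_names = c("sigma", "rho", "beta"))
}

param_filter_spec <- function(pm, a0, a1, SigmaII) {
  cg_model(
    n_I = pm$n_I, n_II = pm$n_par,
    A0 = pm$A0, A1 = pm$A1_lambda,
    a0 = function(t, uI) a0,
    a1 = function(t, uI) a1,
    SigmaI = pm$SigmaI,
    SigmaII = function(t, uI) SigmaII,
    state_names_II = pm$par_names,
    name = "param_augmented")
}

param_estimate <- function(pm, fp, traj, window) {
  keep <- fp$t >= window[1] & fp$t <= window[2]
  var_path <- t(apply(fp$cov, 3, diag))
  if (pm$n_par == 1) var_path <- matrix(fp$cov[1, 1, ], ncol = 1)
  structure(list(names = pm$par_names, t = fp$t,
                 mean_path = fp$mean, var_path = var_path,
                 point_estimate = colMeans(fp$mean[keep, , drop = FALSE]),
                 window = window, iterates = NULL, converged = NA,
                 n_iter = NA_integer_),
            class = "cg_param_estimate")
}

#' @export
print.cg_param_estimate <- function(x, ...) {
  cat("<cg_param_estimate>\n")
  est <- x$point_estimate
  names(est) <- x$names
  print(est)
  if (!is.null(x$iterates))
    cat(sprintf("  fixed-point iterations: %d (converged: %s)\n",
                x$n_iter, x$converged))
  invisible(x)
}

#' Direct parameter estimation by state augmentation
#'
#' Augments the observed system with the trivial parameter dynamics
#' `dLambda = 0` and runs the conditional Gaussian filter: the parameter
#' posterior covariance has no positive source term, so the posterior
#' variance is non-increasing and (under observability) the mean converges
#' to the truth.
#'
#' @param pm a [param_model()].
#' @param traj observed `cg_trajectory`.
#' @param prior_mean,prior_cov Gaussian prior on the parameters.
#' @param window time window over which the point estimate averages
#'   (default the final 80 percent of the record).
#' @return a `cg_param_estimate`.
#' @export
estimate_direct <- function(pm, traj, prior_mean = rep(0, pm$n_par),
                            prior_cov = diag(1, pm$n_par),
                            window = NULL) {
  spec <- param_filter_spec(pm, a0 = rep(0, pm$n_par),
                            a1 = matrix(0, pm$n_par, pm$n_par),
                            SigmaII = rep(0, pm$n_par))
  fp <- filter_posterior(spec, traj, init_mean = prior_mean,
                         init_cov = prior_cov)
  Tend <- max(traj$t)
  window <- window %||% c(Tend / 5, Tend)
  param_estimate(pm, fp, traj, window)
}

#' Parameter estimation with stochastic parameterized equations
#'
#' Augments each unknown parameter with an Ornstein--Uhlenbeck prior
#' process `dLambda_i = -d_i (Lambda_i - hat_i) dt + s_i dW` and filters.
#' The biased-but-informative prior dynamics greatly accelerate convergence
#' compared with the direct scheme; the point estimate is the time average
#' of the posterior mean over `window`.
#'
#' @inheritParams estimate_direct
#' @param ou_d,ou_mean,ou_sigma per-parameter OU damping (positive),
#'   equilibrium mean and noise amplitude.
#' @param init_mean,init_cov filter initialization.
#' @export
estimate_stochastic_param <- function(pm, traj, ou_d, ou_mean, ou_sigma,
                                      init_mean = rep(0, pm$n_par),
                                      init_cov = diag(1, pm$n_par),
                                      window = NULL) {
  if (length(ou_d) == 1) ou_d <- rep(ou_d, pm$n_par)
  stopifnot(all(ou_d >= 0), length(ou_mean) == pm$n_par,
            length(ou_sigma) == pm$n_par)
  spec <- param_filter_spec(pm, a0 = ou_d * ou_mean, a1 = diag(-ou_d, pm$n_par),
                            SigmaII = ou_sigma)
  fp <- filter_posterior(spec, traj, init_mean = init_mean,
                         init_cov = init_cov)
  Tend <- max(traj$t)
  window <- window %||% c(Tend / 5, Tend)
  param_estimate(pm, fp, traj, window)
}

#' Fixed-point estimation of unresolved-process parameters
#'
#' Estimates the parameters `(sigma_gamma, d_gamma, gamma_hat)` of a hidden
#' scalar Ornstein--Uhlenbeck damping process from an observed trajectory of
#' the resolved mode alone (the SPEKF-M structure
#' `du = (-gamma u + F) dt + sigma_u dW`).  Each iteration filters the
#' hidden damping with the current parameters, pools the conditional
#' Gaussians over time instants into an equilibrium Gaussian mixture, and
#' matches the hidden process's stationary mean, variance and decorrelation
#' time:
#' `gamma_hat <- mean of the conditional means`,
#' `d_gamma <- 1 / (integrated autocorrelation time of the conditional
#' mean)`, `sigma_gamma <- sqrt(2 d_gamma R_eq)` with
#' `R_eq = mean(R(t) + (mu(t) - mu_eq)^2)`.
#'
#' @param traj observed `cg_trajectory` of the resolved mode.
#' @param init initial parameter triple `(sigma_gamma, d_gamma, gamma_hat)`.
#' @param sigma_u,F known resolved-mode noise amplitude and forcing.
#' @param max_iter iteration cap.
#' @param rtol relative-change convergence threshold on all three
#'   parameters.
#' @param burn_frac initial fraction of the record dropped from the
#'   equilibrium averages.
#' @return a `cg_param_estimate` with the iteration table in `$iterates`.
#' @export
estimate_unresolved_fixed_point <- function(traj, init = c(0.1, 1, 2.5),
                                            sigma_u = 0.5, F = 2,
                                            max_iter = 10, rtol = 1e-2,
                                            burn_frac = 0.02) {
  par <- c(sigma_gamma = init[1], d_gamma = init[2], gamma_hat = init[3])
  iterates <- matrix(par, 1, 3, dimnames = list(NULL, names(par)))
  converged <- FALSE
  n_iter <- 0L
  keep <- seq_len(nrow(traj$uI)) > burn_frac * nrow(traj$uI)
  fp <- NULL
  for (it in seq_len(max_iter)) {
    spec <- build_spekf_m(sigma_gamma = par[1], d_gamma = par[2],
                          gamma_hat = par[3], sigma_u = sigma_u, F = F)
    fp <- filter_posterior(spec, traj, init_mean = par[3],
                           init_cov = matrix(par[1]^2 / (2 * par[2])))
    mu <- fp$mean[keep, 1]
    Rt <- fp$cov[1, 1, keep]
    mu_eq <- mean(mu)
    R_eq <- mean(Rt + (mu - mu_eq)^2)
    if (R_eq < 0) stop("negative equilibrium variance estimate")
    tau_eq <- integrated_act(mu, traj$dt)
    new <- c(sigma_gamma = sqrt(2 * R_eq / tau_eq),
             d_gamma = 1 / tau_eq, gamma_hat = mu_eq)
    iterates <- rbind(iterates, new)
    n_iter <- it
    rel <- abs(new - par) / pmax(abs(par), 1e-12)
    par <- new
    if (all(rel < rtol)) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fixed-point iteration did not converge in ", max_iter,
            " iterations")
  est <- structure(list(names = c("sigma_gamma", "d_gamma", "gamma_hat"),
                        t = fp$t, mean_path = fp$mean,
                        var_path = matrix(fp$cov[1, 1, ], ncol = 1),
                        point_estimate = par,
                        window = range(traj$t[keep]),
                        iterates = iterates, converged = converged,
                        n_iter = n_iter),
                   class = "cg_param_estimate")
  est
}
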