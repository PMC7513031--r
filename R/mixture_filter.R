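# Conditional-Gaussian-mixture particle filter analysis step: particles for
# the low-dimensional large-scale state, each carrying a Gaussian law for
# the small scales, updated by per-particle Kalman analysis and likelihood
# reweighting.

#' Conditional Gaussian mixture prior
#'
#' Forecast distribution of the multiscale particle filter: `Q` particles
#' for the large-scale state, each carrying the conditional Gaussian law of
#' the small-scale state.
#'
#' @param particles `Q x N1` matrix of large-scale particle states.
#' @param weights particle weights (normalized internally).
#' @param cond_means `Q x N2` matrix of per-particle small-scale conditional
#'   means.
#' @param cond_covs list of `Q` conditional covariance matrices (or a single
#'   matrix shared by all particles).
#' @return a `cg_mixture_prior`.
#' @export
mixture_prior <- function(particles, weights = NULL, cond_means, cond_covs) {
  if (!is.matrix(particles)) particles <- matrix(particles, ncol = 1)
  if (!is.matrix(cond_means)) cond_means <- matrix(cond_means, ncol = 1)
  Q <- nrow(particles)
  if (is.null(weights)) weights <- rep(1 / Q, Q)
  stopifnot(length(weights) == Q, all(weights >= 0), nrow(cond_means) == Q)
  if (!is.list(cond_covs)) cond_covs <- rep(list(as.matrix(cond_covs)), Q)
  stopifnot(length(cond_covs) == Q)
  structure(list(particles = particles, weights = weights / sum(weights),
                 cond_means = cond_means, cond_covs = cond_covs, Q = Q),
            class = "cg_mixture_prior")
}

#' Mixed large/small-scale linear observation
#'
#' Observation `v = Gbar ubar + Gprime(ubar) uprime + noise`, mixing the
#' large-scale state and the small-scale fluctuations, with Gaussian noise
#' covariance `r_theta`.
#'
#' @param v observed vector (length `M`).
#' @param Gbar `M x N1` matrix acting on the large-scale state.
#' @param Gprime `M x N2` matrix, or function of the large-scale particle
#'   returning one; must have full row rank `M`.
#' @param r_theta `M x M` symmetric positive-definite observation-noise
#'   covariance.
#' @export
linear_mixed_obs <- function(v, Gbar, Gprime, r_theta) {
  Gbar <- as.matrix(Gbar); r_theta <- as.matrix(r_theta)
  stopifnot(nrow(Gbar) == length(v), all(dim(r_theta) == length(v)),
            isTRUE(all.equal(r_theta, t(r_theta))))
  if (min(eigen(r_theta, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("r_theta must be positive definite")
  if (!is.function(Gprime)) {
    Gp <- as.matrix(Gprime)
    Gprime <- function(ubar) Gp
  }
  structure(list(v = v, Gbar = Gbar, Gprime = Gprime, r_theta = r_theta,
                 M = length(v)),
            class = "cg_mixed_obs")
}

#' Analysis step of the conditional Gaussian mixture particle filter
#'
#' Per particle `j`: Kalman gain
#' `K' = R' G'^T (G' R' G'^T + r_theta)^{-1}`, posterior conditional
#' mean/covariance from the standard Kalman update with innovation
#' `v - Gbar ubar_j - G'(ubar_j) u'_j`, and weight update
#' `p_j^a  proportional to  p_j^f I_j` where the marginal likelihood `I_j`
#' is evaluated in closed form as the Gaussian density of `v` with mean
#' `Gbar ubar_j + G'(ubar_j) u'_j` and covariance `G' R' G'^T + r_theta`
#' (the integral over the conditional Gaussian is itself Gaussian).
#'
#' @param prior a [mixture_prior()].
#' @param obs a [linear_mixed_obs()].
#' @return the posterior `cg_mixture_prior` (large-scale particles
#'   unchanged; conditional means/covariances and weights updated).
#' @export
analysis_update <- function(prior, obs) {
  Q <- prior$Q
  logI <- numeric(Q)
  means_a <- prior$cond_means
  covs_a <- vector("list", Q)
  for (j in seq_len(Q)) {
    ub <- prior$particles[j, ]
    up <- prior$cond_means[j, ]
    R <- prior$cond_covs[[j]]
    Gp <- obs$Gprime(ub)
    if (qr(Gp)$rank < obs$M)
      stop("Gprime(ubar) is rank deficient (rank < M); refusing to update")
    S <- Gp %*% R %*% t(Gp) + obs$r_theta
    Kg <- R %*% t(Gp) %*% solve(S)
    pred <- drop(obs$Gbar %*% ub) + drop(Gp %*% up)
    innov <- obs$v - pred
    means_a[j, ] <- up + drop(Kg %*% innov)
    covs_a[[j]] <- symmetrize((diag(1, nrow(R)) - Kg %*% Gp) %*% R)
    logI[j] <- dmvnorm_log(obs$v, pred, S)
  }
  lw <- log(prior$weights) + logI
  if (all(!is.finite(lw))) {
    warning("all particle likelihoods underflowed; falling back to uniform weights")
    w <- rep(1 / Q, Q)
  } else {
    lw <- lw - max(lw)
    w <- exp(lw) / sum(exp(lw))
  }
  mixture_prior(prior$particles, w, means_a, covs_a)
}

#' Resample the particle mixture
#'
#' Multinomial resampling of the large-scale particles (with their attached
#' conditional Gaussians) when the effective sample size `1 / sum(w^2)`
#' falls below `ess_threshold * Q`; weights reset to `1/Q`.
#'
#' @param posterior a [mixture_prior()].
#' @param ess_threshold fraction of `Q` below which resampling triggers.
#' @param seed optional RNG seed for reproducibility.
#' @export
resample_particles <- function(posterior, ess_threshold = 0.5, seed = NULL) {
  w <- posterior$weights
  ess <- 1 / sum(w^2)
  if (ess / posterior$Q >= ess_threshold) return(posterior)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(posterior$Q, posterior$Q, replace = TRUE, prob = w)
  mixture_prior(posterior$particles[idx, , drop = FALSE], NULL,
                posterior$cond_means[idx, , drop = FALSE],
                posterior$cond_covs[idx])
}

#' Overall mean and covariance of a conditional Gaussian mixture prior
#'
#' @param prior a [mixture_prior()].
#' @return list with the mixture mean and covariance of the small-scale
#'   state.
#' @export
mixture_prior_moments <- function(prior) {
  w <- prior$weights
  m <- drop(w %*% prior$cond_means)
  S <- matrix(0, ncol(prior$cond_means), ncol(prior$cond_means))
  for (j in seq_len(prior$Q)) {
    d <- prior$cond_means[j, ] - m
    S <- S + w[j] * (prior$cond_covs[[j]] + tcrossprod(d))
  }
  list(mean = m, cov = S)
}
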