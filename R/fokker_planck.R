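# Statistically accurate hybrid solver for the time-dependent PDF of a
# conditional Gaussian system: an ensemble of L observed trajectories
# carries (i) a kernel density estimate on the low-dimensional observed
# subspace and (ii) the exact conditional Gaussian law on the hidden
# subspace, so the joint PDF is a Gaussian mixture of L tensor-product
# components.

# run the ensemble and the per-member filter once; everything else wraps this
cg_ensemble_state <- function(spec, L, t_eval, u0, dt = spec$default_dt,
                              seed = 1, init_cov = 0, blocked = FALSE) {
  trajs <- ensemble_simulate(spec, u0, L, T = t_eval, dt = dt, seed = seed,
                             keep_uII = FALSE)
  nt <- length(trajs[[1]]$t)
  hid_means <- matrix(NA_real_, L, spec$n_II)
  hid_covs <- vector("list", L)
  uI_ends <- matrix(NA_real_, L, spec$n_I)
  for (l in seq_len(L)) {
    u0l <- if (is.function(u0)) u0(l) else u0
    init_mean <- u0l[spec$n_I + seq_len(spec$n_II)]
    fp <- if (blocked)
      filter_posterior_blocked(spec, trajs[[l]], init_mean = init_mean,
                               init_cov_blocks = init_cov)
    else
      filter_posterior(spec, trajs[[l]], init_mean = init_mean,
                       init_cov = diag(init_cov, spec$n_II))
    hid_means[l, ] <- fp$mean[nt, ]
    hid_covs[[l]] <- filter_cov_at(fp, nt)
    uI_ends[l, ] <- trajs[[l]]$uI[nt, ]
  }
  list(uI_ends = uI_ends, hid_means = hid_means, hid_covs = hid_covs)
}

#' Hidden-subspace marginal PDF from the hybrid solver
#'
#' Generates `L` independent observed trajectories, runs the closed-form
#' conditional Gaussian filter along each, and returns the equal-weight
#' mixture of the `L` conditional Gaussians at `t_eval` -- the parametric
#' estimate of the hidden marginal of the Fokker--Planck solution.
#'
#' @param spec a [cg_model()].
#' @param L ensemble size (>= 1).
#' @param t_eval evaluation time.
#' @param u0 initial full state (or sampler `function(l)`); a deterministic
#'   `u0` means the initial conditional law is a point mass.
#' @param dt integration step.
#' @param seed RNG seed.
#' @param init_cov initial conditional covariance (scalar diagonal).
#' @param blocked use the block-decomposed filter.
#' @return a [gaussian_mixture()] of kind `"conditional-hidden"`.
#' @export
hidden_marginal <- function(spec, L, t_eval, u0, dt = spec$default_dt,
                            seed = 1, init_cov = 0, blocked = FALSE) {
  st <- cg_ensemble_state(spec, L, t_eval, u0, dt, seed, init_cov, blocked)
  gaussian_mixture(st$hid_means, st$hid_covs, kind = "conditional-hidden")
}

#' Joint PDF from the hybrid strategy
#'
#' Each of the `L` mixture components is the tensor product of a Gaussian
#' kernel on the observed subspace (mean at the trajectory endpoint,
#' diagonal plug-in bandwidth covariance) and the trajectory's conditional
#' Gaussian on the hidden subspace.  Marginalizing a component over either
#' subspace is exact, so [mixture_marginal()] of the result recovers the
#' kernel density estimate of the observed marginal and the conditional
#' Gaussian mixture of the hidden marginal, component by component.
#'
#' @inheritParams hidden_marginal
#' @param bandwidth optional kernel bandwidths for the observed subspace.
#' @return a [gaussian_mixture()] of kind `"joint"` over
#'   `(uI, uII)` (observed coordinates first).
#' @export
hybrid_joint <- function(spec, L, t_eval, u0, dt = spec$default_dt,
                         seed = 1, init_cov = 0, blocked = FALSE,
                         bandwidth = NULL) {
  st <- cg_ensemble_state(spec, L, t_eval, u0, dt, seed, init_cov, blocked)
  if (is.null(bandwidth)) bandwidth <- kde_bandwidth(st$uI_ends)
  nI <- spec$n_I; nII <- spec$n_II
  covs <- lapply(seq_len(L), function(l) {
    S <- matrix(0, nI + nII, nI + nII)
    S[seq_len(nI), seq_len(nI)] <- diag(bandwidth^2, nI)
    S[nI + seq_len(nII), nI + seq_len(nII)] <- st$hid_covs[[l]]
    S
  })
  gaussian_mixture(cbind(st$uI_ends, st$hid_means), covs, kind = "joint")
}

#' Augment site-wise conditional Gaussians under statistical symmetry
#'
#' On a statistically homogeneous lattice every site has the same law, so
#' the `K` site-wise Gaussians of a single run act as `K` samples (effective
#' ensemble size `K L`).  With `offset = 0` the result is the 1-d marginal
#' mixture; with `offset > 0` a 2-d joint is built by pairing each site with
#' the site `offset` positions along (cyclic wrap for the last pairs) with
#' diagonal per-component covariance -- the spatial correlation is carried
#' by how the paired means are distributed, not by the component covariance.
#'
#' @param spec the lattice [cg_model()] (must be flagged statistically
#'   symmetric).
#' @param site_means,site_vars length-`K` vectors of per-site conditional
#'   means and variances (use zero variance with observed-site values and a
#'   kernel bandwidth squared as `site_vars` for the observed field).
#' @param offset site pairing offset (0 for a 1-d marginal).
#' @return a [gaussian_mixture()].
#' @export
symmetry_augment <- function(spec, site_means, site_vars, offset = 0) {
  if (!isTRUE(spec$symmetric))
    stop("model '", spec$name,
         "' is not flagged statistically symmetric; refusing to pool sites")
  K <- length(site_means)
  stopifnot(length(site_vars) == K, all(site_vars >= 0))
  if (offset == 0)
    return(gaussian_mixture(matrix(site_means, ncol = 1),
                            matrix(site_vars, ncol = 1),
                            kind = "conditional-hidden"))
  j <- cyc(seq_len(K) + as.integer(offset), K)
  gaussian_mixture(cbind(site_means, site_means[j]),
                   cbind(site_vars, site_vars[j]),
                   kind = "joint")
}
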