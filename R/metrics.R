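#' Path-wise skill measures
#'
#' Root-mean-square error and pattern (anomaly) correlation between a true
#' path and its estimate.
#'
#' @param truth,estimate numeric vectors of equal length.
#' @return scalar.
#' @export
rmse <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  sqrt(mean((estimate - truth)^2))
}

#' @rdname rmse
#' @export
pattern_correlation <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  a <- estimate - mean(estimate); b <- truth - mean(truth)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Relative entropy (Kullback--Leibler divergence)
#'
#' The lack of information in the model density `pM` relative to the truth
#' `p`.  Two forms are supported: the Gaussian closed form
#' \deqn{\tfrac12[\log(\det R_M/\det R) + \mathrm{tr}(R_M^{-1}R) - d +
#'   (\bar u_M-\bar u)^T R_M^{-1}(\bar u_M-\bar u)]}
#' when both arguments are lists with `mean` and `cov`, and trapezoid
#' quadrature when both are density vectors on a shared grid `x` (1-d) or
#' matrix grid (2-d with `dx` the cell area).  Densities are floored at
#' 1e-300 before the logarithm; if more than 1e-4 of the truth mass sits on
#' floored model cells the result is `Inf` with attribute `flagged`.
#'
#' @param p,pM either densities on the shared grid, or
#'   `list(mean = , cov = )` Gaussian descriptions.
#' @param x grid (vector) for quadrature; alternatively supply `dx`.
#' @param dx cell width/area for pre-tabulated densities.
#' @return scalar `>= 0` (up to quadrature error).
#' @export
relative_entropy <- function(p, pM, x = NULL, dx = NULL) {
  if (is.list(p) && !is.null(p$mean)) {
    stopifnot(is.list(pM), !is.null(pM$mean))
    R <- as.matrix(p$cov); RM <- as.matrix(pM$cov)
    d <- length(p$mean)
    RMi <- solve(RM)
    dm <- pM$mean - p$mean
    return(0.5 * (determinant(RM)$modulus - determinant(R)$modulus +
                    sum(diag(RMi %*% R)) - d +
                    drop(t(dm) %*% RMi %*% dm))[[1]])
  }
  stopifnot(length(p) == length(pM))
  if (is.null(dx)) {
    stopifnot(!is.null(x), length(x) == length(p))
    w <- numeric(length(x))
    dxs <- diff(x)
    w[1] <- dxs[1] / 2; w[length(x)] <- dxs[length(dxs)] / 2
    if (length(x) > 2) w[2:(length(x) - 1)] <- (dxs[-1] + dxs[-length(dxs)]) / 2
  } else {
    w <- rep(dx, length(p))
  }
  pf <- pmax(p, 0)
  floored <- pM < 1e-300 & pf > 0
  mass_floored <- sum(pf[floored] * w[floored])
  pMf <- pmax(pM, 1e-300)
  val <- sum(ifelse(pf > 0, pf * log(pf / pMf), 0) * w)
  if (mass_floored > 1e-4) {
    val <- Inf
    attr(val, "flagged") <- TRUE
  }
  val
}

#' Shannon entropy of the estimation residual
#'
#' Entropy of the distribution of `U = truth - estimate`, an information
#' surrogate of the RMSE.  With `gaussian = TRUE` the closed form
#' `0.5 log(2 pi e var(U))` is used; otherwise the residual density is
#' estimated by a Gaussian kernel density estimate and its entropy computed
#' by quadrature.
#'
#' @inheritParams rmse
#' @param gaussian use the Gaussian closed form.
#' @param n_grid quadrature resolution for the KDE route.
#' @export
shannon_entropy_residual <- function(truth, estimate, gaussian = FALSE,
                                     n_grid = 2^12) {
  U <- truth - estimate
  if (gaussian) return(0.5 * log(2 * pi * exp(1) * stats::var(U)))
  h <- kde_bandwidth(U)
  g <- seq(min(U) - 8 * h, max(U) + 8 * h, length.out = n_grid)
  mix <- observed_marginal(U, bandwidth = h)
  dens <- pmax(mixture_density(mix, g), 1e-300)
  -trapz(g, dens * log(dens))
}

#' Mutual information between truth and estimate
#'
#' Computed through the identity `M = P(p(u, uM), pi(u) pi(uM))`: the
#' relative entropy of the joint density with respect to the product of its
#' marginals (so the Gibbs inequality guarantees `M >= 0`).  With
#' `gaussian = TRUE` the closed form `-0.5 log(1 - rho^2)` is used.
#'
#' @inheritParams rmse
#' @param gaussian use the Gaussian closed form.
#' @param n_grid grid resolution per axis for the KDE route.
#' @export
mutual_information <- function(truth, estimate, gaussian = FALSE,
                               n_grid = 128) {
  if (gaussian) {
    rho <- stats::cor(truth, estimate)
    return(-0.5 * log(1 - rho^2))
  }
  hx <- kde_bandwidth(truth); hy <- kde_bandwidth(estimate)
  gx <- seq(min(truth) - 5 * hx, max(truth) + 5 * hx, length.out = n_grid)
  gy <- seq(min(estimate) - 5 * hy, max(estimate) + 5 * hy,
            length.out = n_grid)
  joint <- gaussian_mixture(cbind(truth, estimate),
                            matrix(c(hx^2, hy^2), length(truth), 2,
                                   byrow = TRUE))
  pj <- mixture_density(joint, as.matrix(expand.grid(gx, gy)))
  px <- mixture_density(observed_marginal(truth, hx), gx)
  py <- mixture_density(observed_marginal(estimate, hy), gy)
  prod_marg <- as.vector(outer(px, py))
  dx <- diff(gx[1:2]) * diff(gy[1:2])
  relative_entropy(pj, prod_marg, dx = dx)
}
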