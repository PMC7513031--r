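#' Gaussian mixture probability density
#'
#' Equal- or general-weight mixture of Gaussian components, the container
#' used by the statistically accurate Fokker--Planck solver: the hidden
#' marginal is a mixture of conditional Gaussians, the observed marginal a
#' mixture of kernel Gaussians, and the joint a mixture of their tensor
#' products.
#'
#' @param means `L x d` matrix of component means.
#' @param covs either an `L x d` matrix of per-component diagonal variances,
#'   or a list of `L` full `d x d` covariance matrices.
#' @param weights component weights (default equal); must be non-negative
#'   and are normalized to sum to 1.
#' @param kind tag: one of `"conditional-hidden"`, `"kernel-observed"`,
#'   `"joint"`, `"generic"`.
#' @return object of class `gaussian_mixture`.
#' @export
gaussian_mixture <- function(means, covs, weights = NULL,
                             kind = c("generic", "conditional-hidden",
                                      "kernel-observed", "joint")) {
  kind <- match.arg(kind)
  if (!is.matrix(means)) means <- matrix(means, ncol = 1)
  L <- nrow(means); d <- ncol(means)
  if (is.null(weights)) weights <- rep(1 / L, L)
  stopifnot(length(weights) == L, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  if (is.list(covs)) {
    covs <- lapply(covs, function(S) matrix(S, d, d))
    stopifnot(length(covs) == L)
    diagonal <- FALSE
  } else {
    if (!is.matrix(covs)) covs <- matrix(covs, nrow = L, ncol = d)
    stopifnot(nrow(covs) == L, ncol(covs) == d, all(covs >= 0))
    diagonal <- TRUE
  }
  structure(list(weights = weights, means = means, covs = covs,
                 d = d, L = L, diagonal = diagonal, kind = kind),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("<gaussian_mixture [%s]>  L = %d components in d = %d\n",
              x$kind, x$L, x$d))
  invisible(x)
}

#' Evaluate a Gaussian mixture density
#'
#' @param mix a [gaussian_mixture()].
#' @param x evaluation points: vector (1-d) or `m x d` matrix.
#' @return vector of densities (non-negative).
#' @export
mixture_density <- function(mix, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = mix$d)
  stopifnot(ncol(x) == mix$d)
  m <- nrow(x)
  dens <- numeric(m)
  for (l in seq_len(mix$L)) {
    if (mix$diagonal) {
      v <- pmax(mix$covs[l, ], 1e-300)
      z <- sweep(x, 2, mix$means[l, ], `-`)
      q <- rowSums(sweep(z^2, 2, v, `/`))
      comp <- exp(-q / 2) / prod(sqrt(2 * pi * v))
    } else {
      S <- mix$covs[[l]]
      ch <- chol(S)
      z <- backsolve(ch, t(sweep(x, 2, mix$means[l, ], `-`)),
                     transpose = TRUE)
      q <- colSums(z^2)
      comp <- exp(-q / 2) / ((2 * pi)^(mix$d / 2) * prod(diag(ch)))
    }
    dens <- dens + mix$weights[l] * comp
  }
  dens
}

#' Moments of a Gaussian mixture
#'
#' Closed-form per-coordinate mean, variance, skewness and kurtosis from the
#' weighted combination of component Gaussian moments.
#'
#' @param mix a [gaussian_mixture()].
#' @return data frame with one row per coordinate.
#' @export
mixture_moments <- function(mix) {
  w <- mix$weights
  out <- lapply(seq_len(mix$d), function(j) {
    mu <- mix$means[, j]
    v <- if (mix$diagonal) mix$covs[, j]
         else vapply(mix$covs, function(S) S[j, j], numeric(1))
    m <- sum(w * mu)
    dlt <- mu - m
    m2 <- sum(w * (dlt^2 + v))
    m3 <- sum(w * (dlt^3 + 3 * dlt * v))
    m4 <- sum(w * (dlt^4 + 6 * dlt^2 * v + 3 * v^2))
    data.frame(mean = m, var = m2,
               skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
  })
  cbind(coord = seq_len(mix$d), do.call(rbind, out))
}

#' Marginalize a Gaussian mixture onto a coordinate subset
#'
#' Exact per component: a Gaussian marginal of a Gaussian is obtained by
#' dropping coordinates of the mean and covariance.
#'
#' @param mix a [gaussian_mixture()].
#' @param dims integer coordinate indices to keep.
#' @export
mixture_marginal <- function(mix, dims) {
  stopifnot(all(dims >= 1), all(dims <= mix$d))
  covs <- if (mix$diagonal) mix$covs[, dims, drop = FALSE]
          else lapply(mix$covs, function(S) S[dims, dims, drop = FALSE])
  gaussian_mixture(mix$means[, dims, drop = FALSE], covs,
                   weights = mix$weights, kind = mix$kind)
}

#' Check mixture normalization on an adaptive grid
#'
#' Integrates the density over mean +/- `n_sd` standard deviations with
#' trapezoid quadrature (1-d and 2-d).
#'
#' @param mix a [gaussian_mixture()] with `d <= 2`.
#' @param n_grid grid points per dimension.
#' @param n_sd half-width in overall mixture standard deviations.
#' @return the integral (should be within 1e-3 of 1).
#' @export
mixture_normalization <- function(mix, n_grid = 400, n_sd = 8) {
  mom <- mixture_moments(mix)
  lo <- mom$mean - n_sd * sqrt(mom$var)
  hi <- mom$mean + n_sd * sqrt(mom$var)
  if (mix$d == 1) {
    g <- seq(lo[1], hi[1], length.out = n_grid)
    trapz(g, mixture_density(mix, g))
  } else if (mix$d == 2) {
    gx <- seq(lo[1], hi[1], length.out = n_grid)
    gy <- seq(lo[2], hi[2], length.out = n_grid)
    z <- matrix(mixture_density(mix, as.matrix(expand.grid(gx, gy))),
                n_grid, n_grid)
    dx <- diff(gx[1:2]); dy <- diff(gy[1:2])
    wx <- rep(1, n_grid); wx[c(1, n_grid)] <- 0.5
    sum((wx %o% wx) * z) * dx * dy
  } else stop("normalization check supports d <= 2")
}
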