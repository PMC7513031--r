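#' Simulate a conditional Gaussian system by Euler--Maruyama
#'
#' Integrates the coupled system forward with independent Wiener increments
#' per coordinate.  States falling below a declared lower bound (positivity
#' constraints of population-type models, whose multiplicative noise vanishes
#' at zero but whose discretized drift can still cross it) are clipped to the
#' bound and counted.
#'
#' @param spec a [cg_model()].
#' @param u0 initial full state, length `n_I + n_II`.
#' @param T duration.
#' @param dt time step (> 0); defaults to the model's registry value.
#' @param seed RNG seed recorded in the trajectory.
#' @param keep_uII logical; store the hidden path (default `TRUE`).
#' @return a `cg_trajectory`: list with `t`, `uI` (`(steps+1) x n_I`), `uII`
#'   (or `NULL`), `dt`, `seed` and the clip counter `n_clipped`.
#' @export
simulate_sde <- function(spec, u0, T, dt = spec$default_dt, seed = 1,
                         keep_uII = TRUE) {
  stopifnot(dt > 0, length(u0) == spec$n_I + spec$n_II)
  lower <- c(spec$lower_I %||% rep(-Inf, spec$n_I),
             spec$lower_II %||% rep(-Inf, spec$n_II))
  if (any(u0 < lower)) stop("u0 violates the model's domain constraints")
  nt <- as.integer(round(T / dt))
  tgrid <- seq(0, by = dt, length.out = nt + 1L)
  nI <- spec$n_I; nII <- spec$n_II
  uI_path <- matrix(NA_real_, nt + 1L, nI)
  uII_path <- if (keep_uII && nII > 0) matrix(NA_real_, nt + 1L, nII) else NULL
  u <- u0
  uI_path[1L, ] <- u[seq_len(nI)]
  if (!is.null(uII_path)) uII_path[1L, ] <- u[nI + seq_len(nII)]
  drift <- spec$drift_full
  n_clipped <- 0L
  sqdt <- sqrt(dt)
  bounded <- any(is.finite(lower))
  set.seed(seed)
  for (n in seq_len(nt)) {
    t <- tgrid[n]
    uI <- u[seq_len(nI)]
    SI <- spec$SigmaI(t, uI)
    SII <- spec$SigmaII(t, uI)
    noise <- numeric(nI + nII)
    noise[seq_len(nI)] <- if (is.matrix(SI))
      drop(SI %*% stats::rnorm(nI)) else SI * stats::rnorm(nI)
    if (nII > 0)
      noise[nI + seq_len(nII)] <- if (is.matrix(SII))
        drop(SII %*% stats::rnorm(nII)) else SII * stats::rnorm(nII)
    u <- u + drift(t, u) * dt + noise * sqdt
    if (!all(is.finite(u)))
      stop(sprintf("simulation blew up (non-finite state) at t = %.4f",
                   tgrid[n + 1L]))
    if (bounded && any(u < lower)) {
      n_clipped <- n_clipped + sum(u < lower)
      u <- pmax(u, lower)
    }
    uI_path[n + 1L, ] <- u[seq_len(nI)]
    if (!is.null(uII_path)) uII_path[n + 1L, ] <- u[nI + seq_len(nII)]
  }
  structure(list(t = tgrid, uI = uI_path, uII = uII_path, dt = dt,
                 seed = seed, n_clipped = n_clipped, model = spec$name),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory '%s'>  %d steps, dt = %g, seed = %d",
              x$model, length(x$t) - 1L, x$dt, x$seed))
  if (x$n_clipped > 0) cat(sprintf("  (%d clipped states)", x$n_clipped))
  cat("\n")
  invisible(x)
}

#' Simulate an ensemble of independent trajectories
#'
#' Trajectories use independent RNG sub-streams derived deterministically
#' from `seed`, so a run is bit-reproducible given `(seed, L, dt)`.
#'
#' @param spec a [cg_model()].
#' @param u0 initial state, or a function `(l)` returning the initial state
#'   of member `l`.
#' @param L ensemble size (>= 1).
#' @inheritParams simulate_sde
#' @return list of `L` `cg_trajectory` objects.
#' @export
ensemble_simulate <- function(spec, u0, L, T, dt = spec$default_dt, seed = 1,
                              keep_uII = TRUE) {
  stopifnot(L >= 1)
  seeds <- derive_seeds(seed, L)
  lapply(seq_len(L), function(l) {
    u0l <- if (is.function(u0)) u0(l) else u0
    simulate_sde(spec, u0l, T, dt, seed = seeds[l], keep_uII = keep_uII)
  })
}
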