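#' Exact conditional Gaussian filter
#'
#' Evolves the posterior mean and covariance of the hidden subspace given an
#' observed path, by forward-Euler discretization of the closed-form moment
#' equations
#' \deqn{d\bar u_{II} = [a_0 + a_1 \bar u_{II}]dt +
#'   (R_{II} A_1^*)(\Sigma_I\Sigma_I^*)^{-1}[du_I - (A_0 + A_1\bar u_{II})dt],}
#' \deqn{dR_{II} = \{a_1 R_{II} + R_{II} a_1^* + \Sigma_{II}\Sigma_{II}^* -
#'   (R_{II} A_1^*)(\Sigma_I\Sigma_I^*)^{-1}(R_{II} A_1^*)^*\}dt,}
#' using the observed increments `duI`.  The covariance is symmetrized each
#' step; eigenvalues below `-1e-8` at the final time trigger a warning.
#'
#' @param spec a [cg_model()].
#' @param traj a `cg_trajectory` (only its `uI` path and grid are used).
#' @param init_mean,init_cov initial posterior mean (length `n_II`) and
#'   covariance (`n_II x n_II`, or scalar 0 for a point mass).
#' @param regularize logical; when the observed-noise Gram matrix is
#'   ill-conditioned (condition number above 1e12) add `lambda I` with
#'   `lambda = 1e-10 trace/n`.  Off by default; enable for models with
#'   degenerate observed noise.
#' @param blowup_norm abort threshold on `max(abs(cov))`.
#' @return a `cg_filter_path`: list with `t`, `mean` (`nt x n_II`) and `cov`
#'   (`n_II x n_II x nt` array).
#' @export
filter_posterior <- function(spec, traj, init_mean = rep(0, spec$n_II),
                             init_cov = diag(1, spec$n_II),
                             regularize = FALSE, blowup_norm = 1e8) {
  nI <- spec$n_I; nII <- spec$n_II
  stopifnot(nII > 0, ncol(traj$uI) == nI)
  if (is.null(dim(init_cov))) init_cov <- diag(init_cov, nII)
  stopifnot(length(init_mean) == nII, all(dim(init_cov) == nII))
  nt <- nrow(traj$uI)
  dt <- traj$dt
  mean_path <- matrix(NA_real_, nt, nII)
  cov_path <- array(NA_real_, c(nII, nII, nt))
  m <- init_mean; R <- symmetrize(init_cov)
  mean_path[1L, ] <- m; cov_path[, , 1L] <- R
  for (n in seq_len(nt - 1L)) {
    t <- traj$t[n]
    uI <- traj$uI[n, ]
    duI <- traj$uI[n + 1L, ] - uI
    A0 <- spec$A0(t, uI); A1 <- spec$A1(t, uI)
    a0 <- spec$a0(t, uI); a1 <- spec$a1(t, uI)
    SI <- spec$SigmaI(t, uI); SII <- spec$SigmaII(t, uI)
    G <- R %*% t(A1)                       # n_II x n_I
    if (!is.matrix(SI)) {                  # diagonal observed noise
      q <- SI^2
      bad <- q <= 0 | !is.finite(q)
      if (any(bad)) {
        if (!regularize)
          stop("singular observed-noise matrix in rows: ",
               paste(which(bad), collapse = ", "),
               " (enable regularize = TRUE)")
        q[bad] <- 1e-10 * max(mean(q[!bad]), 1e-12)
      } else if (regularize && max(q) / min(q) > 1e12) {
        q <- q + 1e-10 * mean(q)
      }
      K <- sweep(G, 2, q, `/`)
    } else {
      QI <- SI %*% t(SI)
      if (regularize) {
        ev <- range(abs(diag(QI)))
        if (!all(is.finite(ev)) || kappa(QI) > 1e12)
          QI <- QI + diag(1e-10 * sum(diag(QI)) / nI, nI)
      }
      K <- t(solve(QI, t(G)))
    }
    QII <- sigma_to_cov(SII)
    innov <- duI - (A0 + drop(A1 %*% m)) * dt
    m <- m + (a0 + drop(a1 %*% m)) * dt + drop(K %*% innov)
    R <- R + (a1 %*% R + R %*% t(a1) + QII - K %*% t(G)) * dt
    R <- symmetrize(R)
    if (!all(is.finite(R)) || max(abs(R)) > blowup_norm)
      stop(sprintf("posterior covariance blew up at t = %.4f", traj$t[n + 1L]))
    mean_path[n + 1L, ] <- m
    cov_path[, , n + 1L] <- R
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    warning(sprintf("final posterior covariance has eigenvalue %.3e < -1e-8",
                    min(ev)))
  structure(list(t = traj$t, mean = mean_path, cov = cov_path,
                 blocks = NULL, model = spec$name),
            class = "cg_filter_path")
}

#' Kalman--Bucy filter (linear special case)
#'
#' For linear coupled systems all coefficients depend on time only; the
#' closed-form conditional Gaussian filter then reduces to the classical
#' continuous-time Kalman filter.  This asserts coefficient constancy in the
#' observed state and then runs the shared code path of
#' [filter_posterior()], so the two are identical by construction on linear
#' models.
#'
#' @inheritParams filter_posterior
#' @param n_probe number of random observed states at which constancy is
#'   checked.
#' @export
kalman_bucy <- function(spec, traj, init_mean = rep(0, spec$n_II),
                        init_cov = diag(1, spec$n_II), n_probe = 5, ...) {
  set.seed(0L)
  uI0 <- rep(0.5, spec$n_I)
  for (t in c(traj$t[1], stats::median(traj$t))) {
    ref <- list(spec$A0(t, uI0), spec$A1(t, uI0), spec$a0(t, uI0),
                spec$a1(t, uI0), spec$SigmaI(t, uI0), spec$SigmaII(t, uI0))
    for (p in seq_len(n_probe)) {
      uI <- stats::rnorm(spec$n_I)
      cand <- list(spec$A0(t, uI), spec$A1(t, uI), spec$a0(t, uI),
                   spec$a1(t, uI), spec$SigmaI(t, uI), spec$SigmaII(t, uI))
      dev <- max(mapply(function(a, b) max(c(0, abs(a - b))), ref, cand))
      if (!isTRUE(dev <= 1e-12))
        stop("coefficients depend on the observed state; ",
             "not a linear (Kalman-Bucy) system")
    }
  }
  filter_posterior(spec, traj, init_mean, init_cov, ...)
}

#' Block-decomposed conditional Gaussian filter
#'
#' When the interaction coefficients restricted to block `k` depend only on
#' the block's own observed coordinates and the initial covariance is block
#' diagonal, the conditional covariance stays block diagonal: each block's
#' covariance evolves independently (block updates within a step are
#' order-independent), while the posterior means remain fully coupled
#' through `a0`.  Stores and updates only `sum_k N_{II,k}^2` covariance
#' entries per step instead of `n_II^2`.
#'
#' @inheritParams filter_posterior
#' @param init_cov_blocks list of per-block initial covariance matrices, or
#'   a scalar replicated on every block diagonal.
#' @param check_condition probe the block condition before filtering.
#' @return a `cg_filter_path` with `cov` a list (per block) of
#'   `N_k x N_k x nt` arrays.
#' @export
filter_posterior_blocked <- function(spec, traj,
                                     init_mean = rep(0, spec$n_II),
                                     init_cov_blocks = 1,
                                     check_condition = FALSE,
                                     blowup_norm = 1e8) {
  bl <- spec$blocks
  if (is.null(bl)) stop("model has no block structure")
  if (check_condition && !check_block_condition(spec))
    stop("block condition violated: A1/a1 of some block depend on other blocks' observed state")
  K <- bl$K
  nt <- nrow(traj$uI); dt <- traj$dt
  sizes <- vapply(bl$uII, length, integer(1))
  if (!is.list(init_cov_blocks))
    init_cov_blocks <- lapply(sizes, function(s) diag(init_cov_blocks, s))
  mean_path <- matrix(NA_real_, nt, spec$n_II)
  cov_path <- lapply(sizes, function(s) array(NA_real_, c(s, s, nt)))
  m <- init_mean
  Rk <- lapply(init_cov_blocks, symmetrize)
  mean_path[1L, ] <- m
  for (k in seq_len(K)) cov_path[[k]][, , 1L] <- Rk[[k]]
  for (n in seq_len(nt - 1L)) {
    t <- traj$t[n]
    uI <- traj$uI[n, ]
    duI <- traj$uI[n + 1L, ] - uI
    cf <- blocked_coefs(spec, t, uI)
    m_new <- m
    for (k in seq_len(K)) {
      iI <- bl$uI[[k]]; iII <- bl$uII[[k]]
      A1k <- cf$A1[[k]]; a1k <- cf$a1[[k]]
      R <- Rk[[k]]
      qk <- cf$SI[[k]]^2
      G <- R %*% t(A1k)
      K_g <- sweep(G, 2, qk, `/`)
      innov <- duI[iI] - (cf$A0[iI] + drop(A1k %*% m[iII])) * dt
      m_new[iII] <- m[iII] + (cf$a0[iII] + drop(a1k %*% m[iII])) * dt +
        drop(K_g %*% innov)
      R <- R + (a1k %*% R + R %*% t(a1k) + diag(cf$SII[[k]]^2, length(iII)) -
                  K_g %*% t(G)) * dt
      Rk[[k]] <- symmetrize(R)
      cov_path[[k]][, , n + 1L] <- Rk[[k]]
    }
    m <- m_new
    if (!all(is.finite(m)) || max(abs(m)) > blowup_norm)
      stop(sprintf("posterior mean blew up at t = %.4f", traj$t[n + 1L]))
    mean_path[n + 1L, ] <- m
  }
  structure(list(t = traj$t, mean = mean_path, cov = cov_path,
                 blocks = bl, model = spec$name),
            class = "cg_filter_path")
}

#' @export
print.cg_filter_path <- function(x, ...) {
  cat(sprintf("<cg_filter_path '%s'>  %d steps, n_II = %d%s\n", x$model,
              length(x$t) - 1L, ncol(x$mean),
              if (!is.null(x$blocks)) sprintf(", %d blocks", x$blocks$K) else ""))
  invisible(x)
}

# full covariance at a time index, assembling blocks when needed
filter_cov_at <- function(fp, idx) {
  nII <- ncol(fp$mean)
  if (is.null(fp$blocks)) return(matrix(fp$cov[, , idx], nII, nII))
  R <- matrix(0, nII, nII)
  for (k in seq_len(fp$blocks$K)) {
    iII <- fp$blocks$uII[[k]]
    R[iII, iII] <- matrix(fp$cov[[k]][, , idx], length(iII), length(iII))
  }
  R
}
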