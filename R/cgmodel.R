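#' Conditional Gaussian model specification
#'
#' Defines a coupled stochastic system
#' \deqn{du_I = [A_0(t,u_I) + A_1(t,u_I) u_{II}]\,dt + \Sigma_I(t,u_I)\,dW_I,}
#' \deqn{du_{II} = [a_0(t,u_I) + a_1(t,u_I) u_{II}]\,dt + \Sigma_{II}(t,u_I)\,dW_{II},}
#' in which the hidden subspace \eqn{u_{II}} is Gaussian once conditioned on a
#' realized path of the observed subspace \eqn{u_I}, even though the full
#' system is nonlinear and typically strongly non-Gaussian.
#'
#' All coefficient functions take `(t, uI)` and return arrays of the declared
#' shapes.  The diffusion coefficients may return a plain numeric vector,
#' which is interpreted as the diagonal of the matrix (per-coordinate noise
#' standard deviations).
#'
#' @param n_I,n_II dimensions of the observed and hidden subspaces.
#' @param A0,A1,a0,a1 drift coefficient functions of `(t, uI)`; `A0` returns a
#'   length-`n_I` vector, `A1` an `n_I x n_II` matrix, `a0` a length-`n_II`
#'   vector and `a1` an `n_II x n_II` matrix.
#' @param SigmaI,SigmaII diffusion coefficient functions of `(t, uI)`
#'   returning an `n_I x n_I` (resp. `n_II x n_II`) matrix or a vector of
#'   diagonal standard deviations.
#' @param state_names_I,state_names_II coordinate labels.
#' @param lower_I,lower_II optional per-coordinate lower bounds (e.g.
#'   positivity for population models); `NULL` for unconstrained.
#' @param drift_full optional function `(t, u)` giving the drift of the full
#'   state directly from the model equations.  Used by the structural
#'   validators as an independent cross-check of the coefficient
#'   factorization; defaults to the composition of the coefficients.
#' @param blocks optional [cg_blocks()] partition for block-decomposed
#'   filtering.
#' @param block_coefs optional function `(t, uI)` returning per-block
#'   coefficients (see [filter_posterior_blocked()]); built by slicing the
#'   full coefficients when absent.
#' @param symmetric logical, statistical symmetry across blocks (homogeneous
#'   lattice).
#' @param physics_constrained logical, quadratic nonlinearity conserves
#'   energy (`u . B(u,u) = 0`).
#' @param name,params registry bookkeeping.
#' @param default_dt suggested integration step for [simulate_sde()].
#' @return an object of class `cg_model`.
#' @seealso [build_model()], [simulate_sde()], [filter_posterior()]
#' @export
cg_model <- function(n_I, n_II, A0, A1, a0, a1, SigmaI, SigmaII,
                     state_names_I = paste0("uI", seq_len(n_I)),
                     state_names_II = if (n_II > 0) paste0("uII", seq_len(n_II)) else character(),
                     lower_I = NULL, lower_II = NULL,
                     drift_full = NULL, blocks = NULL, block_coefs = NULL,
                     symmetric = FALSE, physics_constrained = FALSE,
                     name = "custom", params = list(), default_dt = 0.005) {
  stopifnot(n_I >= 1, n_II >= 0)
  m <- structure(list(
    n_I = as.integer(n_I), n_II = as.integer(n_II),
    A0 = A0, A1 = A1, a0 = a0, a1 = a1,
    SigmaI = SigmaI, SigmaII = SigmaII,
    state_names_I = state_names_I, state_names_II = state_names_II,
    lower_I = lower_I, lower_II = lower_II,
    drift_full = drift_full, blocks = blocks, block_coefs = block_coefs,
    symmetric = isTRUE(symmetric),
    physics_constrained = isTRUE(physics_constrained),
    name = name, params = params, default_dt = default_dt
  ), class = "cg_model")
  if (is.null(m$drift_full)) m$drift_full <- compose_drift(m)
  check_shapes(m)
  m
}

# drift of the full state from the coefficient factorization
compose_drift <- function(spec) {
  force(spec)
  function(t, u) {
    uI <- u[seq_len(spec$n_I)]
    uII <- if (spec$n_II > 0) u[spec$n_I + seq_len(spec$n_II)] else numeric(0)
    dI <- spec$A0(t, uI)
    dII <- numeric(0)
    if (spec$n_II > 0) {
      dI <- dI + drop(spec$A1(t, uI) %*% uII)
      dII <- spec$a0(t, uI) + drop(spec$a1(t, uI) %*% uII)
    }
    c(dI, dII)
  }
}

check_shapes <- function(spec, t = 0, uI = NULL) {
  if (is.null(uI)) uI <- rep(0.5, spec$n_I)
  stopifnot(length(spec$A0(t, uI)) == spec$n_I)
  if (spec$n_II > 0) {
    A1 <- spec$A1(t, uI)
    stopifnot(is.matrix(A1), nrow(A1) == spec$n_I, ncol(A1) == spec$n_II)
    stopifnot(length(spec$a0(t, uI)) == spec$n_II)
    a1 <- spec$a1(t, uI)
    stopifnot(is.matrix(a1), nrow(a1) == spec$n_II, ncol(a1) == spec$n_II)
  }
  SI <- spec$SigmaI(t, uI)
  stopifnot((is.matrix(SI) && all(dim(SI) == spec$n_I)) ||
              length(SI) == spec$n_I)
  SII <- spec$SigmaII(t, uI)
  stopifnot((is.matrix(SII) && all(dim(SII) == spec$n_II)) ||
              length(SII) == spec$n_II)
  invisible(TRUE)
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf("<cg_model '%s'>  n_I = %d, n_II = %d\n", x$name, x$n_I, x$n_II))
  if (!is.null(x$blocks))
    cat(sprintf("  blocks: K = %d%s\n", length(x$blocks$uI),
                if (x$symmetric) " (statistically symmetric)" else ""))
  if (x$physics_constrained)
    cat("  physics-constrained (energy-conserving quadratic nonlinearity)\n")
  invisible(x)
}

#' Block partition of a conditional Gaussian system
#'
#' An ordered partition of the observed and hidden coordinates into `K`
#' groups.  When the coefficients satisfy the block condition (the
#' interaction matrices `A1` and `a1` restricted to group `k` depend only on
#' the group's own observed coordinates, and the initial covariance is block
#' diagonal) the conditional covariance stays block diagonal for all time and
#' each block can be evolved independently.
#'
#' @param uI_idx,uII_idx lists of integer index vectors, one per block;
#'   together they must partition `1:n_I` and `1:n_II`.
#' @param symmetric logical, statistical symmetry across blocks.
#' @export
cg_blocks <- function(uI_idx, uII_idx, symmetric = FALSE) {
  stopifnot(length(uI_idx) == length(uII_idx), length(uI_idx) >= 1)
  iI <- sort(unlist(uI_idx)); iII <- sort(unlist(uII_idx))
  if (anyDuplicated(iI) || any(diff(iI) != 1))
    stop("uI_idx must be a disjoint exhaustive partition")
  if (length(iII) && (anyDuplicated(iII) || any(diff(iII) != 1)))
    stop("uII_idx must be a disjoint exhaustive partition")
  structure(list(uI = uI_idx, uII = uII_idx, K = length(uI_idx),
                 symmetric = isTRUE(symmetric)),
            class = "cg_blocks")
}

#' Number of conditional-covariance entries updated per filter step
#'
#' For a blocked filter this is the sum of squared hidden block sizes; for
#' the full filter it is `n_II^2`.  The ratio quantifies the saving from the
#' block decomposition.
#'
#' @param spec a `cg_model`.
#' @param blocked logical; count the blocked or the full representation.
#' @return integer entry count.
#' @export
n_cov_entries <- function(spec, blocked = !is.null(spec$blocks)) {
  if (!blocked) return(spec$n_II^2)
  if (is.null(spec$blocks)) stop("model has no block structure")
  sum(vapply(spec$blocks$uII, function(ix) length(ix)^2, numeric(1)))
}

#' Numerically validate the conditional Gaussian structure
#'
#' Probes the model's full drift (as given by its own equations through
#' `drift_full`) at random states and verifies that it is affine in the
#' hidden coordinates for fixed observed coordinates: second differences
#' along hidden directions must vanish, and the drift must agree with the
#' declared affine coefficients.  The diffusion coefficients take `(t, uI)`
#' only and so cannot depend on the hidden state by construction.
#'
#' @param spec a `cg_model`.
#' @param n_probe number of random probe states (>= 2).
#' @param seed RNG seed for the probes.
#' @param t time at which to probe.
#' @param tol relative tolerance.
#' @return a list with logical entries `A0`, `A1`, `a0`, `a1` and `pass`.
#' @export
validate_cg_structure <- function(spec, n_probe = 10, seed = 1, t = 0,
                                  tol = 1e-8) {
  stopifnot(n_probe >= 2)
  ok <- c(A0 = TRUE, A1 = TRUE, a0 = TRUE, a1 = TRUE)
  if (spec$n_II == 0)
    return(list(A0 = TRUE, A1 = TRUE, a0 = TRUE, a1 = TRUE, pass = TRUE))
  set.seed(seed)
  iI <- seq_len(spec$n_I); iII <- spec$n_I + seq_len(spec$n_II)
  for (p in seq_len(n_probe)) {
    uI <- stats::rnorm(spec$n_I)
    uII <- stats::rnorm(spec$n_II)
    if (!is.null(spec$lower_I)) uI <- pmax(uI, spec$lower_I + 0.1)
    if (!is.null(spec$lower_II)) uII <- pmax(uII, spec$lower_II + 0.1)
    f0 <- spec$drift_full(t, c(uI, rep(0, spec$n_II)))
    scale <- max(1, max(abs(f0)))
    A0 <- spec$A0(t, uI); a0 <- spec$a0(t, uI)
    A1 <- spec$A1(t, uI); a1 <- spec$a1(t, uI)
    # constant part
    if (max(abs(f0[iI] - A0)) > tol * scale) ok["A0"] <- FALSE
    if (max(abs(f0[iII] - a0)) > tol * scale) ok["a0"] <- FALSE
    dirs <- sample.int(spec$n_II, min(spec$n_II, 5L))
    for (j in dirs) {
      e <- rep(0, spec$n_II); e[j] <- max(1, abs(uII[j]))
      fp <- spec$drift_full(t, c(uI, e))
      fm <- spec$drift_full(t, c(uI, -e))
      # curvature along hidden directions must vanish
      curv <- fp + fm - 2 * f0
      if (max(abs(curv[iI])) > tol * scale) ok["A1"] <- FALSE
      if (max(abs(curv[iII])) > tol * scale) ok["a1"] <- FALSE
      # linear part must match declared A1 / a1
      lin <- (fp - fm) / 2
      if (max(abs(lin[iI] - drop(A1 %*% e))) > tol * scale) ok["A1"] <- FALSE
      if (max(abs(lin[iII] - drop(a1 %*% e))) > tol * scale) ok["a1"] <- FALSE
    }
  }
  c(as.list(ok), list(pass = all(ok)))
}

#' Energy residual of the quadratic nonlinearity
#'
#' For physics-constrained models the quadratic part `B(u,u)` of the drift
#' conserves energy, `u . B(u,u) = 0`.  The quadratic part is extracted
#' numerically as the drift minus its affine fit at the origin (exact for
#' quadratic drifts with unit-step central differences); the returned scalar
#' is the energy flux `u . B(u,u)`, zero up to floating-point roundoff for
#' conforming models.
#'
#' @param spec a `cg_model` flagged `physics_constrained`.
#' @param u full state vector (length `n_I + n_II`).
#' @param t time.
#' @return scalar residual.
#' @export
quadratic_energy_residual <- function(spec, u, t = 0) {
  if (!spec$physics_constrained)
    stop("model '", spec$name, "' is not tagged physics-constrained")
  n <- spec$n_I + spec$n_II
  stopifnot(length(u) == n)
  f <- spec$drift_full
  f0 <- f(t, rep(0, n))
  # central differences with unit step are exact for quadratic drifts
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    J[, j] <- (f(t, e) - f(t, -e)) / 2
  }
  B <- f(t, u) - f0 - drop(J %*% u)
  sum(u * B)
}

#' Probe the block condition on the interaction coefficients
#'
#' Checks numerically that `A1` and `a1` restricted to block `k` depend only
#' on the block's own observed coordinates: perturbing observed coordinates
#' outside the block must leave the block's interaction matrices unchanged.
#'
#' @param spec a `cg_model` with a block structure.
#' @param n_probe number of random probes.
#' @param seed RNG seed.
#' @param t time.
#' @param tol absolute tolerance.
#' @return logical, `TRUE` if the condition holds at all probes.
#' @export
check_block_condition <- function(spec, n_probe = 5, seed = 1, t = 0,
                                  tol = 1e-10) {
  if (is.null(spec$blocks)) stop("model has no block structure")
  set.seed(seed)
  bl <- spec$blocks
  for (p in seq_len(n_probe)) {
    uI <- stats::rnorm(spec$n_I)
    if (!is.null(spec$lower_I)) uI <- pmax(uI, spec$lower_I + 0.1)
    c0 <- blocked_coefs(spec, t, uI)
    for (k in seq_len(min(bl$K, 8L))) {
      uI2 <- uI + stats::rnorm(spec$n_I)   # perturb everything ...
      uI2[bl$uI[[k]]] <- uI[bl$uI[[k]]]    # ... except block k's own uI
      c2 <- blocked_coefs(spec, t, uI2)
      if (max(abs(c0$A1[[k]] - c2$A1[[k]])) > tol) return(FALSE)
      if (length(c0$a1[[k]]) &&
          max(abs(c0$a1[[k]] - c2$a1[[k]])) > tol) return(FALSE)
    }
  }
  TRUE
}

# per-block coefficients, via the model's own block_coefs or by slicing
blocked_coefs <- function(spec, t, uI) {
  if (!is.null(spec$block_coefs)) return(spec$block_coefs(t, uI))
  bl <- spec$blocks
  A1 <- spec$A1(t, uI); a1 <- spec$a1(t, uI)
  SI <- spec$SigmaI(t, uI); SII <- spec$SigmaII(t, uI)
  sI <- if (is.matrix(SI)) diag(SI) else SI
  sII <- if (is.matrix(SII)) diag(SII) else SII
  list(
    A0 = spec$A0(t, uI), a0 = spec$a0(t, uI),
    A1 = lapply(seq_len(bl$K), function(k)
      A1[bl$uI[[k]], bl$uII[[k]], drop = FALSE]),
    a1 = lapply(seq_len(bl$K), function(k)
      a1[bl$uII[[k]], bl$uII[[k]], drop = FALSE]),
    SI = lapply(seq_len(bl$K), function(k) sI[bl$uI[[k]]]),
    SII = lapply(seq_len(bl$K), function(k) sII[bl$uII[[k]]])
  )
}
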