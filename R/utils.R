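# internal numerical helpers

# coerce a diffusion coefficient (vector = diagonal std devs, or full matrix)
# to the covariance Sigma Sigma^T
sigma_to_cov <- function(S) {
  if (is.matrix(S)) S %*% t(S) else diag(S^2, nrow = length(S))
}

# x^T applied as quadratic form helpers avoided; keep plain

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

symmetrize <- function(R) (R + t(R)) / 2

# log density of a multivariate normal, cov given as full matrix
dmvnorm_log <- function(x, mean, cov) {
  d <- length(x)
  ch <- chol(cov)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# integrated autocorrelation time: trapezoid over the sample ACF up to its
# first non-positive lag, in time units (equals 1/d for an OU process with
# damping d)
integrated_act <- function(x, dt) {
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(n - 1L, 5000L), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  zc <- which(rho <= 0)
  m <- if (length(zc)) zc[1] else length(rho)
  lags <- seq_len(m) - 1L
  dt * trapz(lags, rho[seq_len(m)])
}

# deterministic sub-stream seeds (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
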