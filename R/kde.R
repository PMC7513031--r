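#' Plug-in kernel bandwidths for the observed subspace
#'
#' Per-dimension "solve-the-equation" plug-in bandwidth (Sheather--Jones),
#' computed with [stats::bw.SJ()].  When the fixed-point solve fails, or
#' with fewer than 8 samples, falls back to Silverman's rule of thumb
#' ([stats::bw.nrd0()]) with a warning.
#'
#' @param samples numeric vector or `L x d` matrix of samples.
#' @return vector of `d` bandwidths (kernel standard deviations).
#' @export
kde_bandwidth <- function(samples) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  apply(samples, 2, function(x) {
    if (length(x) < 8L || stats::sd(x) == 0) {
      warning("fewer than 8 samples or degenerate sample; Silverman fallback")
      return(max(stats::bw.nrd0(x), 1e-12))
    }
    tryCatch(stats::bw.SJ(x, method = "ste"),
             error = function(e) {
               warning("solve-the-equation bandwidth failed (",
                       conditionMessage(e), "); Silverman fallback")
               stats::bw.nrd0(x)
             })
  })
}

#' Kernel density estimate of the observed marginal
#'
#' Gaussian kernel density estimate of the low-dimensional observed subspace
#' from ensemble endpoints: an equal-weight mixture of `L` Gaussian kernels
#' centred at the samples with diagonal bandwidth matrix from
#' [kde_bandwidth()].
#'
#' @param samples `L x d` matrix (or vector) of observed-state samples
#'   (`L >= 2`).
#' @param bandwidth optional vector of kernel standard deviations.
#' @return a [gaussian_mixture()] of kind `"kernel-observed"`.
#' @export
observed_marginal <- function(samples, bandwidth = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  if (is.null(bandwidth)) bandwidth <- kde_bandwidth(samples)
  gaussian_mixture(samples,
                   matrix(bandwidth^2, nrow(samples), ncol(samples),
                          byrow = TRUE),
                   kind = "kernel-observed")
}
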