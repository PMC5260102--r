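# Storey pFDR q-values.

#' Estimate the null proportion pi0
#'
#' Storey's estimator: `pi0(lambda) = #{p > lambda} / (m (1 - lambda))`
#' over a lambda grid, smoothed with a cubic spline and read off at the
#' largest lambda; clipped to (0, 1].
#'
#' @param p p-values in (0, 1].
#' @param lambda evaluation grid.
#' @return pi0 estimate.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  pi0 <- if (length(lambda) >= 4L) {
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else {
    pi0l[length(pi0l)]
  }
  min(max(pi0, 1 / m), 1)
}

#' pFDR q-values
#'
#' `q_i = pi0 * min_{p_j >= p_i} (p_j * m / rank_j)`; with `pi0 = 1`
#' this is exactly the Benjamini-Hochberg adjusted p-value.
#'
#' @param p p-values in (0, 1].
#' @param pi0 fixed null proportion, or `NULL` to estimate with
#'   [estimate_pi0()].
#' @return q-values, same order as `p`.
#' @export
compute_qvalues <- function(p, pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  # evaluation order (m / rank) * p keeps the pi0 = 1 case bit-identical
  # to the Benjamini-Hochberg step-up
  q <- pmin(1, cummin(pi0 * ((m / rank(p, ties.method = "max")[o]) * p[o])))
  q[order(o)]
}
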