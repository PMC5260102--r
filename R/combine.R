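# Fisher's method with dependence correction.
#
# U = sum_i V_i with V_i = -2 log p_i is classical Fisher's statistic;
# under independence U ~ chisq_{2K}. With dependent sources U is
# approximated by a scaled chi-squared eta * chisq_v whose first two
# moments match E[U] = 2K and Var(U) = sum_{ij} cov(V_i, V_j). Pairwise
# covariances come from a quartic polynomial in the (shrunk) correlation
# of the probit-transformed p-values; the diagonal is the analytic
# Var(chisq_2) = 4, which makes the reduction to classical Fisher exact
# when all correlations are zero.

KOST_COEF <- c(a1 = 3.263119, a2 = 0.709866, a3 = 0.026589)

#' Probit transform of a p-value
#'
#' `z = qnorm(1 - p)`, standard normal under the null. Values at or
#' outside (0, 1) are clamped to `[eps, 1 - eps]` with a warning.
#'
#' @param p p-value(s).
#' @param eps clamp width.
#' @return z statistic(s).
#' @export
z_transform <- function(p, eps = 1e-15) {
  bad <- p <= 0 | p >= 1
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE), " p-value(s) clamped to (0,1)")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  stats::qnorm(1 - p)
}

#' Pairwise source correlations from a p-value matrix
#'
#' Pearson correlation of the probit-transformed p-values for each pair
#' of sources over pairwise-complete rows. Pairs with fewer than 3
#' complete observations are treated as independent (correlation 0) with
#' a warning.
#'
#' @param p_matrix candidates x K matrix of p-values, `NA` for missing.
#' @return list with `rho_hat` (K x K) and `n_pairs` (K x K counts of
#'   complete observations).
#' @export
estimate_source_correlations <- function(p_matrix) {
  p_matrix <- as.matrix(p_matrix)
  K <- ncol(p_matrix)
  z <- suppressWarnings(z_transform(p_matrix))
  rho <- diag(1, K); n_pairs <- matrix(nrow(p_matrix), K, K)
  dimnames(rho) <- dimnames(n_pairs) <- list(colnames(p_matrix), colnames(p_matrix))
  pres <- colSums(is.finite(z))
  diag(n_pairs) <- pres
  for (i in seq_len(K)) {
    for (j in seq_len(K)[-seq_len(i)]) {
      ok <- is.finite(z[, i]) & is.finite(z[, j])
      n_pairs[i, j] <- n_pairs[j, i] <- sum(ok)
      if (sum(ok) < 3L) {
        # silent when a source is structurally absent from the panel
        if (sum(ok) > 0L || (pres[i] > 0L && pres[j] > 0L))
          warning("sources ", i, " and ", j,
                  " share < 3 complete rows; treated independent")
        r <- 0
      } else {
        r <- stats::cor(z[ok, i], z[ok, j])
        if (!is.finite(r)) r <- 0
      }
      rho[i, j] <- rho[j, i] <- r
    }
  }
  list(rho_hat = rho, n_pairs = n_pairs)
}

#' Small-sample shrinkage of a correlation estimate
#'
#' `rho_tilde = rho_hat * (1 + (1 - rho_hat^2)/(2n - 1))`; fixed points
#' at -1, 0 and 1.
#'
#' @param rho_hat correlation estimate(s), |rho| <= 1.
#' @param n sample size(s) used for the estimate.
#' @return adjusted correlation(s).
#' @export
shrink_correlation <- function(rho_hat, n) {
  rho_hat * (1 + (1 - rho_hat^2) / (2 * n - 1))
}

#' Covariance of two -2 log p terms from their probit correlation
#'
#' Quartic polynomial `a1 r + a2 r^2 + a3 r^3 + a4 r^4` with
#' a1 = 3.263119, a2 = 0.709866, a3 = 0.026589, a4 = -0.709866/n.
#'
#' @param rho_tilde shrunk correlation(s).
#' @param n sample size(s).
#' @return covariance value(s) on the `-2 log p` scale.
#' @export
cov_minus2logp <- function(rho_tilde, n) {
  KOST_COEF[["a1"]] * rho_tilde + KOST_COEF[["a2"]] * rho_tilde^2 +
    KOST_COEF[["a3"]] * rho_tilde^3 - (KOST_COEF[["a2"]] / n) * rho_tilde^4
}

#' Fit the dependence model for a panel of p-value sources
#'
#' Estimates pairwise correlations, applies the small-sample shrinkage,
#' and evaluates the covariance polynomial. The diagonal of the
#' covariance matrix is fixed at the analytic `Var(chisq_2) = 4`.
#'
#' @inheritParams estimate_source_correlations
#' @return object of class `dependence_model` with `rho_hat`,
#'   `rho_tilde`, `n_pairs`, `cov`.
#' @export
dependence_model <- function(p_matrix) {
  est <- estimate_source_correlations(p_matrix)
  n <- pmax(est$n_pairs, 2L)
  rho_tilde <- shrink_correlation(est$rho_hat, n)
  cv <- cov_minus2logp(rho_tilde, n)
  diag(cv) <- 4
  structure(list(rho_hat = est$rho_hat, rho_tilde = rho_tilde,
                 n_pairs = est$n_pairs, cov = cv),
            class = "dependence_model")
}

#' @export
print.dependence_model <- function(x, ...) {
  K <- ncol(x$cov)
  off <- x$rho_hat[upper.tri(x$rho_hat)]
  cat(sprintf("dependence_model: K = %d, mean |rho_hat| = %.3f\n",
              K, if (length(off)) mean(abs(off)) else 0))
  invisible(x)
}

#' Scaled chi-squared null for the Fisher statistic
#'
#' Moment matching: `eta * v = 2K` and `2 eta^2 v = Var(U)` with
#' `Var(U)` the sum of the covariance matrix over the present sources,
#' giving `eta = Var(U)/(4K)` and `v = 2K/eta`. Independence yields
#' `(eta, v) = (1, 2K)` (classical Fisher); perfect dependence yields
#' `(K, 2)`.
#'
#' @param dep a [dependence_model()] (or any list with a `cov` matrix).
#' @param mask logical vector of present sources (default all).
#' @param eta_floor lower bound for eta when the summed covariance is
#'   non-positive.
#' @return object of class `brown_null` with `eta`, `v`, `K`.
#' @export
brown_null <- function(dep, mask = rep(TRUE, ncol(dep$cov)),
                       eta_floor = 1e-6) {
  K <- sum(mask)
  if (K < 1L) stop("no present sources")
  cv <- dep$cov[mask, mask, drop = FALSE]
  var_u <- sum(cv)
  if (var_u <= 0) {
    warning("non-positive Var(U); eta floored")
    var_u <- 4 * K * eta_floor
  }
  eta <- max(var_u / (4 * K), eta_floor)
  structure(list(eta = eta, v = 2 * K / eta, K = K), class = "brown_null")
}

#' @export
print.brown_null <- function(x, ...) {
  cat(sprintf("brown_null: K = %d, eta = %.4f, v = %.4f\n", x$K, x$eta, x$v))
  invisible(x)
}

#' Combine one vector of p-values under a fitted null
#'
#' `U` is summed over present sources only; the combined p-value is the
#' upper tail of `eta * chisq_v` at `U`, i.e.
#' `pchisq(U/eta, df = v, lower.tail = FALSE)`.
#'
#' @param p numeric vector of p-values, `NA` for missing sources.
#' @param null a [brown_null()] fitted to the same presence pattern.
#' @return list with `U`, `p_combined`, `K_effective`.
#' @export
combine_pvalues <- function(p, null) {
  present <- is.finite(p)
  if (!any(present)) stop("no present p-values to combine")
  if (sum(present) != null$K)
    stop("null fitted for K = ", null$K, " sources but ",
         sum(present), " present")
  U <- sum(-2 * log(p[present]))
  list(U = U,
       p_combined = stats::pchisq(U / null$eta, df = null$v, lower.tail = FALSE),
       K_effective = null$K)
}

#' Combine a matrix of p-values row-wise with per-pattern nulls
#'
#' Fits the dependence model once on the full matrix (the background
#' panel defaults to the candidate set itself) and refits the scaled
#' chi-squared null for each distinct missingness pattern.
#'
#' @param p_matrix candidates x K matrix of p-values, `NA` missing.
#' @param dep optional precomputed [dependence_model()]; fitted from
#'   `p_matrix` when `NULL`.
#' @param eta_floor passed to [brown_null()].
#' @return data.frame with `U`, `p_combined`, `K_effective` per row.
#' @export
combine_pvalue_matrix <- function(p_matrix, dep = NULL, eta_floor = 1e-6) {
  p_matrix <- as.matrix(p_matrix)
  if (is.null(dep)) dep <- dependence_model(p_matrix)
  pattern <- apply(is.finite(p_matrix), 1L, paste, collapse = "")
  nulls <- new.env(parent = emptyenv())
  out <- data.frame(U = rep(NA_real_, nrow(p_matrix)),
                    p_combined = NA_real_, K_effective = NA_integer_)
  for (i in seq_len(nrow(p_matrix))) {
    mask <- is.finite(p_matrix[i, ])
    if (!any(mask)) next
    key <- pattern[i]
    if (is.null(nulls[[key]]))
      nulls[[key]] <- brown_null(dep, mask, eta_floor = eta_floor)
    r <- combine_pvalues(p_matrix[i, ], nulls[[key]])
    out$U[i] <- r$U; out$p_combined[i] <- r$p_combined
    out$K_effective[i] <- r$K_effective
  }
  out
}
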