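# Gene-disease association by multivariate regression of phenotype
# similarities on genotype similarity.
#
# For a candidate gene g and query disease d, each other disease e with
# known gene associations contributes one observation: its p phenotype
# similarities to d (responses) and the genotype similarity x_de between
# {g} and e's gene set (single covariate). A positive common slope across
# the p phenotype measures is evidence that g is associated with d; the
# test statistic on the contrast lambda'beta follows t_{n-2} under the
# Gaussian-noise null.

#' Construct a disease space
#'
#' @param phenotype_sims named list of symmetric disease-by-disease
#'   phenotype-similarity matrices (shared dimnames; values in [0,1]).
#' @param disease_genes named list: disease id -> character vector of
#'   associated genes.
#' @return object of class `disease_space`.
#' @export
disease_space <- function(phenotype_sims, disease_genes) {
  stopifnot(length(phenotype_sims) >= 1)
  ids <- rownames(phenotype_sims[[1]])
  for (m in phenotype_sims) {
    if (!isTRUE(all.equal(rownames(m), ids)) ||
        !isSymmetric(unname(m), tol = 1e-8))
      stop("phenotype similarity matrices must be symmetric with shared disease ids")
  }
  structure(list(diseases = ids, phenotype_sims = phenotype_sims,
                 disease_genes = disease_genes),
            class = "disease_space")
}

#' @export
print.disease_space <- function(x, ...) {
  cat(sprintf("disease_space: %d diseases, %d phenotype measures, %d with gene sets\n",
              length(x$diseases), length(x$phenotype_sims),
              sum(lengths(x$disease_genes) > 0)))
  invisible(x)
}

#' Genotype similarity between two gene sets
#'
#' Sum of pairwise gene functional similarities over the Cartesian
#' product of the two sets. Gene pairs missing from the matrix
#' contribute zero.
#'
#' @param D,E character vectors of gene ids.
#' @param phi symmetric gene-by-gene functional-similarity matrix.
#' @return non-negative scalar.
#' @export
genotype_similarity <- function(D, E, phi) {
  D <- D[D %in% rownames(phi)]
  E <- E[E %in% colnames(phi)]
  if (!length(D) || !length(E)) return(0)
  sum(phi[D, E, drop = FALSE])
}

#' Assemble regression inputs for one candidate gene / query disease
#'
#' One row per disease other than the query that has a non-empty gene
#' set; responses are the query disease's phenotype similarities to that
#' disease, the covariate its genotype similarity to the candidate gene.
#' With `leave_out = TRUE` (the evaluation protocol) the candidate gene
#' and all known genes of the query disease are removed from every other
#' disease's gene set first.
#'
#' @param gene candidate gene id.
#' @param disease query disease id.
#' @param space a [disease_space()].
#' @param phi gene functional-similarity matrix.
#' @param leave_out remove the query disease's known genes (and the
#'   candidate) from other diseases' gene sets.
#' @param min_n minimum number of rows (>= 3 for n-2 >= 1 df).
#' @return list with `Y` (n x p), `x` (length n), `row_ids`.
#' @export
build_regression_inputs <- function(gene, disease, space, phi,
                                    leave_out = TRUE, min_n = 3L) {
  if (!disease %in% space$diseases)
    stop("disease '", disease, "' not in the disease space")
  drop_genes <- if (leave_out)
    unique(c(gene, space$disease_genes[[disease]])) else character(0)
  others <- setdiff(space$diseases, disease)
  gsets <- lapply(space$disease_genes[others], setdiff, y = drop_genes)
  keep <- lengths(gsets) > 0
  others <- others[keep]; gsets <- gsets[keep]
  n <- length(others)
  if (n < min_n)
    stop("insufficient data: ", n, " usable diseases (< ", min_n, ")")
  x <- vapply(gsets, function(E) genotype_similarity(gene, E, phi), numeric(1))
  Y <- vapply(space$phenotype_sims,
              function(m) m[disease, others], numeric(n))
  list(Y = matrix(Y, nrow = n,
                  dimnames = list(others, names(space$phenotype_sims))),
       x = unname(x), row_ids = others)
}

#' Maximum-likelihood fit of the multivariate similarity regression
#'
#' Closed-form MLE for p responses sharing the single centred covariate:
#' `beta = (xc'xc)^{-1} xc'Yc`, `alpha = ybar - xbar beta`,
#' `Sigma_eps = E'E/(n-2)` with `E = Yc - xc beta'`.
#'
#' @param inputs a [build_regression_inputs()] list (fields `Y`, `x`).
#' @return object of class `regression_fit` with `alpha_hat`, `beta_hat`
#'   (length-p), `sigma_eps_hat` (p x p), `sxx` (`sum((x - xbar)^2)`),
#'   `n`, `p`.
#' @export
fit_mle <- function(inputs) {
  Y <- as.matrix(inputs$Y); x <- inputs$x
  n <- nrow(Y); p <- ncol(Y)
  if (n < 3L) stop("need n >= 3 observations")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("degenerate design: genotype similarity is constant")
  Yc <- sweep(Y, 2L, colMeans(Y))
  beta <- drop(crossprod(xc, Yc)) / sxx
  alpha <- colMeans(Y) - mean(x) * beta
  E <- Yc - outer(xc, beta)
  sigma <- crossprod(E) / (n - 2)
  structure(list(alpha_hat = alpha, beta_hat = beta, sigma_eps_hat = sigma,
                 sxx = sxx, n = n, p = p),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: n = %d, p = %d\n", x$n, x$p))
  cat("  beta_hat:", signif(x$beta_hat, 4), "\n")
  invisible(x)
}

#' One-sided association test on a slope contrast
#'
#' Tests H0: lambda'beta = 0 against H1: lambda'beta > 0 with
#' `T = lambda'beta_hat / sqrt(lambda' (xc'xc)^{-1} Sigma_hat lambda)`,
#' which follows t_{n-2} under H0; the analytical p-value is the
#' upper-tail probability.
#'
#' @param fit a [fit_mle()] result.
#' @param lambda weight vector over the p phenotype measures
#'   (default all ones).
#' @return list with `T`, `p_analytical`, `se` (the denominator),
#'   `df = n - 2`, `lambda`.
#' @export
association_test <- function(fit, lambda = rep(1, fit$p)) {
  stopifnot(length(lambda) == fit$p)
  s2 <- drop(crossprod(lambda, fit$sigma_eps_hat %*% lambda)) / fit$sxx
  if (s2 <= 0 || !is.finite(s2))
    stop("degenerate fit: zero residual variance in the lambda direction")
  T <- sum(lambda * fit$beta_hat) / sqrt(s2)
  list(T = T,
       p_analytical = stats::pt(T, df = fit$n - 2, lower.tail = FALSE),
       se = sqrt(s2), df = fit$n - 2, lambda = lambda)
}

#' Analytical association p-values of one gene over several similarity measures
#'
#' Runs the full regression-and-test chain once per gene
#' functional-similarity measure; measures whose regression cannot be
#' built or tested (too few usable diseases, constant covariate, zero
#' residual variance, gene absent from the matrix) yield `NA`.
#'
#' @inheritParams build_regression_inputs
#' @param measures named list of gene-similarity matrices.
#' @param lambda contrast weights (default all ones).
#' @return named numeric vector of analytical p-values with `NA` for
#'   unavailable measures.
#' @export
gene_association_pvalues <- function(gene, disease, space, measures,
                                     leave_out = TRUE, lambda = NULL) {
  vapply(measures, function(phi) {
    tryCatch({
      inp <- build_regression_inputs(gene, disease, space, phi,
                                     leave_out = leave_out)
      fit <- fit_mle(inp)
      lam <- if (is.null(lambda)) rep(1, fit$p) else lambda
      association_test(fit, lam)$p_analytical
    }, error = function(e) NA_real_)
  }, numeric(1))
}
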