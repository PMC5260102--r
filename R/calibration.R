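# Orientation of heterogeneous functional scores and rank-based
# calibration to empirical p-values against empirical null panels.

#' Default functional-score configuration
#'
#' Eight whole-genome scores apply to all four retained regions; six
#' protein-function scores apply to coding (EXON) variants only. SIFT and
#' LRT score on a [0,1] scale where *smaller* means more deleterious and
#' are re-oriented as 1 - score; every other score already points in the
#' higher-is-worse direction.
#'
#' @return data.frame with columns `name`, `direction`
#'   (`HIGHER_WORSE`/`LOWER_WORSE`), `unit_scale` (logical: scored on
#'   [0,1], so LOWER_WORSE is flipped as `1 - x` rather than negated) and
#'   `regions` (comma-separated applicable regions).
#' @export
default_score_definitions <- function() {
  all4 <- "EXON,PROMOTER,INTRON,SPLICE_SITE"
  wg <- c("CADD", "DANN", "FATHMM-MKL", "Eigen", "GERP", "phastCons",
          "SiPhy", "PhyloP")
  prot <- c("MutationAssessor", "SIFT", "LRT", "MSRV", "PolyPhen2", "SinBaD")
  data.frame(
    name = c(wg, prot),
    direction = ifelse(c(wg, prot) %in% c("SIFT", "LRT"),
                       "LOWER_WORSE", "HIGHER_WORSE"),
    unit_scale = c(wg, prot) %in% c("SIFT", "LRT"),
    regions = c(rep(all4, length(wg)), rep("EXON", length(prot))),
    stringsAsFactors = FALSE
  )
}

score_regions <- function(defs) {
  stats::setNames(strsplit(defs$regions, ",", fixed = TRUE), defs$name)
}

#' Orient a raw score so that higher means more deleterious
#'
#' @param name score name (must be present in `defs`).
#' @param raw numeric raw score(s).
#' @param defs score configuration, see [default_score_definitions()].
#' @return oriented score(s).
#' @export
orient_score <- function(name, raw, defs = default_score_definitions()) {
  i <- match(name, defs$name)
  if (is.na(i)) stop("score '", name, "' is not configured")
  if (defs$direction[i] == "HIGHER_WORSE") return(raw)
  if (defs$unit_scale[i]) 1 - raw else -raw
}

#' Build an empirical null distribution for one score
#'
#' Sorted panel of oriented scores with known causal variants removed.
#'
#' @param values named (by variant key) or unnamed numeric scores.
#' @param exclude variant keys of known causal variants to drop.
#' @param score_name label stored with the panel.
#' @param min_n minimum panel size.
#' @return object of class `null_distribution` with fields `score_name`,
#'   `values` (sorted ascending) and `n`.
#' @export
build_empirical_null <- function(values, exclude = character(0),
                                 score_name = "score", min_n = 100L) {
  if (length(exclude) && !is.null(names(values)))
    values <- values[!names(values) %in% exclude]
  values <- as.numeric(values[is.finite(values)])
  if (length(values) < min_n)
    stop("insufficient null panel for '", score_name, "': ",
         length(values), " < ", min_n)
  structure(list(score_name = score_name, values = sort(values),
                 n = length(values)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution '%s': n = %d, range [%.4g, %.4g]\n",
              x$score_name, x$n, x$values[1], x$values[x$n]))
  invisible(x)
}

#' Empirical p-value of an oriented score
#'
#' Smoothed upper-tail rank p-value `(r + 1)/(n + 1)` where `r` is the
#' number of null scores greater than or equal to the query (ties count
#' as more extreme). The smoothing keeps p strictly positive, as required
#' by the downstream `-2 log p` transform.
#'
#' @param null a [build_empirical_null()] panel.
#' @param s oriented query score(s).
#' @return p-value(s) in `[1/(n+1), 1]`.
#' @export
empirical_p_value <- function(null, s) {
  # values sorted ascending: count >= s via findInterval on the strict left
  r <- null$n - findInterval(s, null$values, left.open = TRUE)
  (r + 1) / (null$n + 1)
}

#' Calibrate a gene-level analytical p-value against a neutral-gene null
#'
#' "More extreme" for a p-value means smaller, so the empirical p is
#' `(r + 1)/(n + 1)` with `r` the count of neutral-gene analytical
#' p-values less than or equal to the query.
#'
#' @param null_analytical numeric vector of analytical p-values of
#'   neutral genes (need not be sorted).
#' @param p_analytical query analytical p-value(s) in `[0, 1]`.
#' @return empirical p-value(s).
#' @export
calibrate_gene_p <- function(null_analytical, p_analytical) {
  null_analytical <- sort(as.numeric(null_analytical[is.finite(null_analytical)]))
  n <- length(null_analytical)
  if (n == 0L) stop("empty null panel of analytical p-values")
  r <- findInterval(p_analytical, null_analytical)  # count <= query
  (r + 1) / (n + 1)
}
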