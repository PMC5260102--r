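# Spike-in evaluation metrics: rank ratio, mean rank ratio (MRR), rank
# ROC AUC and top-k counts, plus the one-sided enrichment test on the
# top of a ranking.

#' Rank-based metrics for spiked-in causal variants
#'
#' Each causal variant's rank ratio is its rank divided by the number of
#' neutral variants it was ranked against. The rank ROC sweeps a ratio
#' threshold over all observed ratios: the true-positive rate is the
#' fraction of causal ratios at or below the threshold, the
#' false-positive rate the same fraction for neutral ratios; the AUC is
#' the trapezoid area. Neutral ranks default to the complement of the
#' causal rank within each run of `n_neutral + 1` candidates (the
#' one-spike design).
#'
#' @param causal_ranks integer ranks of causal variants (one per
#'   spike-in run).
#' @param n_neutral number of neutral variants per run.
#' @param k top-list cutoff for the TOP count.
#' @param neutral_ranks optional explicit neutral ranks (pooled).
#' @return list with `rank_ratios`, `mrr`, `auc`, `top_k`.
#' @export
compute_rank_metrics <- function(causal_ranks, n_neutral, k = 10L,
                                 neutral_ranks = NULL) {
  if (!length(causal_ranks)) stop("no causal ranks supplied")
  stopifnot(all(causal_ranks >= 1), n_neutral >= 1)
  ratios <- causal_ranks / n_neutral
  if (is.null(neutral_ranks))
    neutral_ranks <- unlist(lapply(causal_ranks, function(r)
      setdiff(seq_len(n_neutral + 1L), r)))
  neutral_ratios <- neutral_ranks / n_neutral
  thr <- sort(unique(c(0, ratios, neutral_ratios)))
  tpr <- vapply(thr, function(t) mean(ratios <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neutral_ratios <= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(rank_ratios = ratios, mrr = mean(ratios), auc = auc,
       top_k = sum(causal_ranks <= k))
}

#' One-sided enrichment p-value for functional variants in a top list
#'
#' Hypergeometric upper tail `P(X >= x)` for
#' `X ~ Hypergeometric(N, K_func, n_top)` — the one-sided Fisher exact
#' p-value of the 2x2 top/rest by functional/other table.
#'
#' @param N total candidates.
#' @param K_func number of functional candidates.
#' @param n_top size of the top list.
#' @param x functional candidates observed in the top list.
#' @return p-value.
#' @export
enrichment_p <- function(N, K_func, n_top, x) {
  if (x < 0 || x > min(K_func, n_top) || n_top > N || K_func > N)
    stop("inconsistent counts: x must lie in [0, min(K_func, n_top)] and K_func, n_top <= N")
  stats::phyper(x - 1, K_func, N - K_func, n_top, lower.tail = FALSE)
}
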