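# End-to-end orchestration: annotate -> calibrate -> associate ->
# combine -> rank.

#' Bundle the resources a prioritization run needs
#'
#' @param transcripts list of [transcript_model()].
#' @param genome reference genome ([read_genome()]).
#' @param score_table data.frame with column `key` plus one raw-score
#'   column per configured source (`NA` for missing).
#' @param null_panels named list of [build_empirical_null()] panels of
#'   *oriented* scores, one per source.
#' @param space a [disease_space()].
#' @param gene_measures named list of gene functional-similarity matrices.
#' @param neutral_genes gene ids not associated with any disease, used
#'   as the empirical null for gene-level analytical p-values.
#' @param score_defs score configuration
#'   ([default_score_definitions()]).
#' @param promoter_window,lambda,leave_out,pi0,eta_floor tuning options;
#'   `pi0 = NULL` estimates the null proportion, `pi0 = 1` gives
#'   Benjamini-Hochberg-equivalent q-values.
#' @return list of class `glints_resources`.
#' @export
glints_resources <- function(transcripts, genome, score_table, null_panels,
                             space, gene_measures, neutral_genes,
                             score_defs = default_score_definitions(),
                             promoter_window = 500L, lambda = NULL,
                             leave_out = TRUE, pi0 = NULL, eta_floor = 1e-6) {
  structure(list(transcripts = transcripts, genome = genome,
                 score_table = score_table, null_panels = null_panels,
                 space = space, gene_measures = gene_measures,
                 neutral_genes = neutral_genes, score_defs = score_defs,
                 promoter_window = promoter_window, lambda = lambda,
                 leave_out = leave_out, pi0 = pi0, eta_floor = eta_floor),
            class = "glints_resources")
}

# calibrated gene-level p-values for one gene: analytical p per measure,
# then rank-calibrated against the neutral-gene analytical null
gene_level_pvalues <- function(gene, disease, res, gene_null) {
  pa <- gene_association_pvalues(gene, disease, res$space, res$gene_measures,
                                 leave_out = res$leave_out, lambda = res$lambda)
  vapply(names(res$gene_measures), function(m) {
    if (!is.finite(pa[[m]]) || !length(gene_null[[m]])) return(NA_real_)
    calibrate_gene_p(gene_null[[m]], pa[[m]])
  }, numeric(1))
}

#' Prioritize candidate SNVs for a query disease
#'
#' Runs the four-stage workflow: (1) region classification and host-gene
#' assignment; (2) region-appropriate functional scores oriented and
#' calibrated to empirical p-values; (3) gene-disease association
#' p-values from the phenotype-similarity regression, calibrated against
#' neutral genes; (4) dependence-corrected Fisher combination and pFDR
#' q-values. A variant hosted by several genes is scored against each
#' and keeps its best (smallest) combined p-value.
#'
#' @param variants a [genomic_variants()] table (or a VCF path, read via
#'   [read_snvs()]).
#' @param disease query disease identifier (must be in the disease
#'   space).
#' @param res a [glints_resources()] bundle.
#' @return list with `ranked` (one row per retained variant: region,
#'   gene, per-source p-values, `U`, `p_combined`, `q_value`, `rank`,
#'   sorted by rank), `discarded` (keys and reasons) and `dep` (the
#'   fitted [dependence_model()]).
#' @export
run_prioritization <- function(variants, disease, res) {
  if (is.character(variants) && length(variants) == 1L)
    variants <- read_snvs(variants)$variants
  if (!disease %in% res$space$diseases) {
    near <- utils::head(res$space$diseases[order(utils::adist(disease, res$space$diseases))], 3)
    stop("unknown disease '", disease, "'; nearest: ", paste(near, collapse = ", "))
  }
  ann <- classify_variants(variants, res$transcripts, res$genome,
                           promoter_window = res$promoter_window,
                           per_gene = TRUE)
  disc_keys <- ann$key[ann$region == "DISCARD"]
  discarded <- data.frame(key = disc_keys,
                          reason = rep("outside retained regions",
                                       length(disc_keys)),
                          stringsAsFactors = FALSE)
  hits <- ann[ann$region != "DISCARD", , drop = FALSE]
  if (!nrow(hits)) {
    warning("no variants retained after region classification")
    return(list(ranked = data.frame(), discarded = discarded, dep = NULL))
  }

  # stage 2: variant-level empirical p-values (per variant key)
  defs <- res$score_defs
  regions_of <- score_regions(defs)
  st <- res$score_table
  row_of <- match(hits$key, st$key)
  vp <- matrix(NA_real_, nrow(hits), nrow(defs),
               dimnames = list(NULL, defs$name))
  for (s in defs$name) {
    if (!s %in% names(st) || is.null(res$null_panels[[s]])) next
    applicable <- hits$region %in% regions_of[[s]]
    raw <- st[[s]][row_of]
    use <- applicable & is.finite(raw)
    if (any(use))
      vp[use, s] <- empirical_p_value(res$null_panels[[s]],
                                      orient_score(s, raw[use], defs))
  }

  # stage 3: gene-level calibrated p-values, computed once per gene
  gene_null <- lapply(names(res$gene_measures), function(m) {
    pa <- vapply(res$neutral_genes, function(g)
      gene_association_pvalues(g, disease, res$space,
                               res$gene_measures[m],
                               leave_out = res$leave_out,
                               lambda = res$lambda)[[1]], numeric(1))
    pa[is.finite(pa)]
  })
  names(gene_null) <- names(res$gene_measures)
  genes <- unique(hits$gene_id)
  gp <- t(vapply(genes, function(g) gene_level_pvalues(g, disease, res, gene_null),
                 numeric(length(res$gene_measures))))
  colnames(gp) <- paste0("gene_", names(res$gene_measures))

  # stage 4: dependence-corrected combination over all sources
  p_matrix <- cbind(vp, gp[match(hits$gene_id, genes), , drop = FALSE])
  dep <- dependence_model(p_matrix)
  comb <- combine_pvalue_matrix(p_matrix, dep, eta_floor = res$eta_floor)

  full <- cbind(hits, as.data.frame(p_matrix), comb)
  # best assignment per variant: smallest combined p, then larger U
  o <- order(full$key, full$p_combined, -full$U, full$gene_id)
  full <- full[o, , drop = FALSE]
  best <- full[!duplicated(full$key), , drop = FALSE]

  best$q_value <- compute_qvalues(best$p_combined, pi0 = res$pi0)
  o <- order(best$p_combined, -best$U, best$key)
  best <- best[o, , drop = FALSE]
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  list(ranked = best, discarded = discarded, dep = dep)
}
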