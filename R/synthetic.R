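# Synthetic world: toy gene models on a random chromosome, a correlated
# functional-score database with planted causal enrichment, and a
# disease space with a planted gene-disease signal. Emulates, at desk
# scale, the spike-in design used to benchmark the prioritizer: every
# generated artifact re-reads through the package's own readers.

#' Simulate a correlated functional-score database
#'
#' Neutral scores are drawn from a Gaussian copula with the target
#' correlation and standard-normal marginals; causal rows get a declared
#' per-source mean shift (in the oriented, higher-is-worse direction).
#'
#' @param n_variants number of rows.
#' @param corr K x K positive semidefinite target correlation.
#' @param causal_shift scalar or length-K oriented mean shift for causal
#'   rows.
#' @param n_causal number of causal rows (placed first).
#' @param missing_rate per-entry missingness probability.
#' @param seed optional RNG seed.
#' @return list with `scores` (n x K matrix, oriented scale) and
#'   `is_causal` (logical vector).
#' @export
simulate_score_database <- function(n_variants, corr, causal_shift = 0,
                                    n_causal = 0, missing_rate = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  corr <- as.matrix(corr)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("target correlation matrix is not positive semidefinite")
  K <- ncol(corr)
  scores <- MASS::mvrnorm(n_variants, mu = rep(0, K), Sigma = corr)
  if (n_variants == 1L) scores <- matrix(scores, 1L)
  is_causal <- seq_len(n_variants) <= n_causal
  if (n_causal > 0)
    scores[is_causal, ] <- sweep(scores[is_causal, , drop = FALSE], 2L,
                                 rep(causal_shift, length.out = K), `+`)
  if (missing_rate > 0)
    scores[matrix(stats::runif(n_variants * K) < missing_rate,
                  n_variants, K)] <- NA_real_
  colnames(scores) <- colnames(corr)
  list(scores = scores, is_causal = is_causal)
}

#' Simulate a disease space with a planted gene-disease signal
#'
#' Gene functional similarities are drawn once per measure (symmetric
#' uniform, unit diagonal); every disease except the query gets 1-3
#' associated genes from a pool disjoint from the transcribed loci.
#' Phenotype similarities follow the generative regression
#' `y = alpha + slope * x + noise` (truncated to [0, 1]), where `x` is
#' the genotype similarity computed with the query disease's *hidden*
#' causal gene; the released disease-gene map leaves the query disease
#' empty.
#'
#' @param n_diseases number of diseases (>= 10); the first is the query.
#' @param loci gene ids of transcribed loci (first is the causal gene).
#' @param pool_genes gene ids assignable to diseases.
#' @param slope planted regression slope (0 for a null space).
#' @param alpha intercept of the generative regression.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_phenotype number of phenotype-similarity measures.
#' @param n_gene_measures number of gene functional-similarity measures.
#' @param seed optional RNG seed.
#' @return list with `space` ([disease_space()]), `measures` (named list
#'   of gene-similarity matrices), `neutral_genes` (loci unattached to
#'   any disease) and `truth` (`query_disease`, `causal_gene`, `slope`).
#' @export
simulate_disease_space <- function(n_diseases = 40,
                                   loci = sprintf("G%02d", 1:20),
                                   pool_genes = sprintf("H%02d", 1:40),
                                   slope = 0.15, alpha = 0.2, noise_sd = 0.1,
                                   n_phenotype = 3, n_gene_measures = 3,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_diseases < 10) stop("need at least 10 diseases")
  genes <- c(loci, pool_genes)
  measures <- lapply(seq_len(n_gene_measures), function(m) {
    M <- matrix(stats::runif(length(genes)^2), length(genes),
                dimnames = list(genes, genes))
    M <- (M + t(M)) / 2
    diag(M) <- 1
    M
  })
  names(measures) <- paste0("sim", seq_len(n_gene_measures))
  diseases <- sprintf("D%02d", seq_len(n_diseases))
  query <- diseases[1L]
  causal_gene <- loci[1L]
  gene_sets <- c(list(character(0)),
                 lapply(seq_len(n_diseases - 1L), function(i)
                   sample(pool_genes, sample(1:3, 1))))
  names(gene_sets) <- diseases
  hidden <- gene_sets
  hidden[[query]] <- causal_gene
  xbar <- matrix(0, n_diseases, n_diseases, dimnames = list(diseases, diseases))
  for (i in seq_len(n_diseases - 1L)) for (j in seq.int(i + 1L, n_diseases)) {
    x <- mean(vapply(measures, function(phi)
      genotype_similarity(hidden[[i]], hidden[[j]], phi), numeric(1)))
    xbar[i, j] <- xbar[j, i] <- x
  }
  if (stats::sd(xbar[upper.tri(xbar)]) == 0)
    stop("degenerate settings: genotype similarities all equal")
  phen <- lapply(seq_len(n_phenotype), function(m) {
    y <- alpha + slope * xbar +
      matrix(stats::rnorm(n_diseases^2, sd = noise_sd), n_diseases)
    y[lower.tri(y)] <- t(y)[lower.tri(y)]
    y <- pmin(pmax(y, 0), 1)
    diag(y) <- 1
    dimnames(y) <- list(diseases, diseases)
    y
  })
  names(phen) <- paste0("phen", seq_len(n_phenotype))
  list(space = disease_space(phen, gene_sets),
       measures = measures,
       neutral_genes = loci[-1L],
       truth = list(query_disease = query, causal_gene = causal_gene,
                    slope = slope, alpha = alpha, noise_sd = noise_sd))
}

# Toy locus layout: 4 exons of 90 bp separated by 30 bp introns; the
# first and last 30 exonic bp are UTRs, so the CDS has 300 bp (100
# codons). Loci alternate strand and sit `spacing` bp apart, leaving the
# 500 bp upstream promoter windows intergenic.
make_toy_transcripts <- function(n_loci = 20, spacing = 3000L, offset = 1000L,
                                 chrom = "chr1") {
  lapply(seq_len(n_loci), function(i) {
    s <- offset + (i - 1L) * spacing
    starts <- s + c(0L, 120L, 240L, 360L)
    ends <- starts + 90L
    strand <- if (i %% 2L == 1L) "+" else "-"
    utr_left <- if (strand == "+") 30L else 0L
    utr_right <- if (strand == "+") 0L else 30L
    transcript_model(sprintf("G%02d", i), chrom, strand,
                     starts, ends,
                     cds_start = starts[1L] + utr_left,
                     cds_end = ends[4L] - utr_right)
  })
}

# enumerate candidate positions (0-based) per region class for one locus
region_pools_of <- function(t) {
  cds <- {
    s <- pmax(t$exon_starts, t$cds_start); e <- pmin(t$exon_ends, t$cds_end)
    unlist(lapply(which(e > s), function(i) seq.int(s[i], e[i] - 1L)))
  }
  intr <- transcript_introns(t)
  splice <- integer(0); intron <- integer(0)
  for (k in seq_len(nrow(intr))) {
    s <- intr[k, "start"]; e <- intr[k, "end"]
    pos <- seq.int(s, e - 1L)
    off <- pmin(pos - s + 1L, e - pos)
    splice <- c(splice, pos[off <= 2L])
    intron <- c(intron, pos[off >= 3L & off <= 10L])
  }
  upstream <- if (t$strand == "+") seq.int(t$tss - 500L, t$tss - 1L)
              else seq.int(t$tss, t$tss + 499L)
  utr <- transcript_utrs(t)
  utr_pos <- unlist(lapply(c(utr["utr5"], utr["utr3"]), function(iv)
    unlist(lapply(seq_len(nrow(iv)), function(i)
      seq.int(iv[i, "start"], iv[i, "end"] - 1L)))))
  list(EXON = cds, SPLICE_SITE = splice, INTRON = intron,
       PROMOTER = c(upstream, utr_pos))
}

synthetic_score_definitions <- function() {
  all4 <- "EXON,PROMOTER,INTRON,SPLICE_SITE"
  nm <- c(paste0("wgs", 1:8), paste0("prot", 1:6))
  data.frame(
    name = nm,
    direction = ifelse(nm == "prot6", "LOWER_WORSE", "HIGHER_WORSE"),
    unit_scale = FALSE,
    regions = c(rep(all4, 8), rep("EXON", 6)),
    stringsAsFactors = FALSE
  )
}

#' Build a complete synthetic world
#'
#' Assembles every input the pipeline needs: a random chromosome with
#' toy gene models, per-source empirical null panels drawn from the
#' score copula, a disease space with a planted signal for the causal
#' gene hosted at the first locus, and region position pools for
#' spike-in candidate generation.
#'
#' @param seed RNG seed; the world is fully reproducible from it.
#' @param n_loci transcribed loci on the toy chromosome.
#' @param n_diseases diseases in the space (first is the query).
#' @param score_corr pairwise score correlation (equicorrelated copula).
#' @param causal_shift oriented mean shift of causal variants, in null
#'   standard deviations.
#' @param missing_rate per-entry score missingness.
#' @param n_null null-panel size per score.
#' @param slope,alpha,noise_sd generative regression parameters of the
#'   disease space.
#' @return list of class `synthetic_world`.
#' @export
synthetic_world <- function(seed = 1L, n_loci = 20, n_diseases = 40,
                            score_corr = 0.3, causal_shift = 1.5,
                            missing_rate = 0.05, n_null = 4000,
                            slope = 0.15, alpha = 0.2, noise_sd = 0.1) {
  set.seed(seed)
  transcripts <- make_toy_transcripts(n_loci)
  chrom_len <- 1000L + n_loci * 3000L + 1000L
  genome <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = ""))
  names(genome) <- "chr1"
  defs <- synthetic_score_definitions()
  K <- nrow(defs)
  corr <- matrix(score_corr, K, K, dimnames = list(defs$name, defs$name))
  diag(corr) <- 1
  null_scores <- simulate_score_database(n_null, corr)$scores
  null_panels <- lapply(defs$name, function(s)
    build_empirical_null(null_scores[, s], score_name = s))
  names(null_panels) <- defs$name
  ds <- simulate_disease_space(n_diseases = n_diseases,
                               loci = vapply(transcripts, `[[`, "", "gene_id"),
                               slope = slope, alpha = alpha,
                               noise_sd = noise_sd)
  pools <- lapply(c(EXON = "EXON", SPLICE_SITE = "SPLICE_SITE",
                    INTRON = "INTRON", PROMOTER = "PROMOTER"),
                  function(r) {
    do.call(rbind, lapply(transcripts, function(t)
      data.frame(gene = t$gene_id, pos0 = region_pools_of(t)[[r]],
                 stringsAsFactors = FALSE)))
  })
  structure(list(seed = seed, genome = genome, transcripts = transcripts,
                 pools = pools, score_defs = defs, score_corr = corr,
                 causal_shift = causal_shift, missing_rate = missing_rate,
                 null_panels = null_panels, space = ds$space,
                 gene_measures = ds$measures,
                 neutral_genes = ds$neutral_genes, truth = ds$truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world (seed %d): %d loci, %d diseases, ",
                     "%d score sources, causal gene %s\n"),
              x$seed, length(x$transcripts), length(x$space$diseases),
              nrow(x$score_defs), x$truth$causal_gene))
  invisible(x)
}

# oriented latent scores -> raw scores as a score-table data.frame
latent_to_score_table <- function(keys, latent, defs) {
  raw <- latent
  flip <- defs$direction == "LOWER_WORSE"
  raw[, flip] <- ifelse(matrix(rep(defs$unit_scale[flip], each = nrow(raw)),
                               nrow(raw)),
                        1 - raw[, flip], -raw[, flip])
  cbind(data.frame(key = keys, stringsAsFactors = FALSE), as.data.frame(raw))
}

#' Generate a spike-in candidate set
#'
#' Samples `n_neutral` control SNVs from the requested region's position
#' pool plus one causal variant placed in the causal gene, draws their
#' functional scores from the world's copula (causal row shifted), and
#' masks protein-score columns outside coding regions.
#'
#' @param world a [synthetic_world()].
#' @param region target region class.
#' @param n_neutral number of control variants.
#' @param seed optional RNG seed for this draw.
#' @return list with `variants` ([genomic_variants()] table),
#'   `score_table` (key + one raw-score column per source) and
#'   `causal_key`.
#' @export
simulate_candidates <- function(world, region = "EXON", n_neutral = 500,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- world$pools[[region]]
  if (is.null(pool) || !nrow(pool)) stop("no positions available for region ", region)
  causal_gene <- world$truth$causal_gene
  tx_of <- stats::setNames(world$transcripts,
                           vapply(world$transcripts, `[[`, "", "gene_id"))
  ctx_cache <- new.env(parent = emptyenv())
  # admissible alternate alleles at one pooled position (sorted, so the
  # (position, alt_rank) pair maps deterministically to one variant)
  alts_at <- function(i) {
    p <- pool$pos0[i]
    ref <- genome_fetch(world$genome, "chr1", p, p + 1L)
    others <- sort(setdiff(c("A", "C", "G", "T"), ref))
    if (region != "EXON") return(list(ref = ref, alts = others))
    g <- pool$gene[i]
    if (is.null(ctx_cache[[g]]))
      ctx_cache[[g]] <- cds_context(tx_of[[g]], world$genome)
    ok <- vapply(others, function(a)
      is_nonsynonymous_ctx(p, ref, a, tx_of[[g]], ctx_cache[[g]],
                           count_stop = TRUE)$nonsynonymous, logical(1))
    list(ref = ref, alts = others[ok])
  }
  # pool expanded to (position, alt_rank) pairs; ranks pointing past the
  # number of admissible alleles are dropped by rejection
  exp_pos <- rep(seq_len(nrow(pool)), 3L)
  exp_rank <- rep(1:3, each = nrow(pool))
  cexp <- which(pool$gene[exp_pos] == causal_gene)
  if (!length(cexp)) stop("causal gene has no positions in region ", region)
  n_total <- n_neutral + 1L
  if (length(exp_pos) < n_total)
    stop("region ", region, " pool too small for ", n_neutral, " controls")
  draw <- c(sample(cexp, 1L),
            sample(setdiff(seq_along(exp_pos), cexp[1]), n_neutral))
  ref <- character(n_total); alt <- character(n_total)
  pending <- seq_len(n_total)
  while (length(pending)) {
    still_bad <- integer(0)
    for (i in pending) {
      aa <- alts_at(exp_pos[draw[i]])
      if (exp_rank[draw[i]] <= length(aa$alts)) {
        ref[i] <- aa$ref
        alt[i] <- aa$alts[exp_rank[draw[i]]]
      } else {
        still_bad <- c(still_bad, i)
      }
    }
    if (length(still_bad)) {
      avail <- setdiff(seq_along(exp_pos), draw)
      for (i in still_bad) {
        src <- if (i == 1L) intersect(avail, cexp) else avail
        if (!length(src)) stop("region ", region, " pool exhausted")
        pick <- if (length(src) == 1L) src else sample(src, 1L)
        draw[i] <- pick
        avail <- setdiff(avail, pick)
      }
    }
    pending <- still_bad
  }
  pos0 <- pool$pos0[exp_pos[draw]]
  genes <- pool$gene[exp_pos[draw]]
  variants <- genomic_variants("chr1", pos0 + 1L, ref, alt)
  db <- simulate_score_database(nrow(variants), world$score_corr,
                                causal_shift = world$causal_shift,
                                n_causal = 1L,
                                missing_rate = world$missing_rate)
  latent <- db$scores
  if (region != "EXON")  # protein scores exist for coding variants only
    latent[, world$score_defs$regions == "EXON"] <- NA_real_
  st <- latent_to_score_table(variants$key, latent, world$score_defs)
  causal_key <- variants$key[1L]
  o <- sample(nrow(variants))
  list(variants = variants[o, , drop = FALSE],
       score_table = st,
       causal_key = causal_key)
}

#' Resource bundle for a synthetic world
#'
#' @param world a [synthetic_world()].
#' @param score_table candidate score table from [simulate_candidates()].
#' @param ... overrides passed to [glints_resources()].
#' @return a [glints_resources()] bundle.
#' @export
world_resources <- function(world, score_table, ...) {
  glints_resources(transcripts = world$transcripts, genome = world$genome,
                   score_table = score_table,
                   null_panels = world$null_panels, space = world$space,
                   gene_measures = world$gene_measures,
                   neutral_genes = world$neutral_genes,
                   score_defs = world$score_defs, ...)
}
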