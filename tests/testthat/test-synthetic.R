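test_that("the score copula hits its target correlation and rejects non-PSD input", {
  db <- simulate_score_database(10000, diag(1, 4), seed = 71)
  r <- stats::cor(db$scores)
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
  corr <- matrix(0.5, 3, 3); diag(corr) <- 1
  db2 <- simulate_score_database(10000, corr, seed = 72)
  expect_equal(mean(stats::cor(db2$scores)[upper.tri(diag(3))]), 0.5,
               tolerance = 0.05)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_score_database(10, bad), "positive semidefinite")
})

test_that("zero causal shift leaves causal rows exchangeable with neutral", {
  db <- simulate_score_database(4000, diag(1, 2), causal_shift = 0,
                                n_causal = 2000, seed = 73)
  ks <- stats::ks.test(db$scores[db$is_causal, 1],
                       db$scores[!db$is_causal, 1])
  expect_gt(ks$p.value, 0.001)
  shifted <- simulate_score_database(4000, diag(1, 2), causal_shift = 1.5,
                                     n_causal = 2000, seed = 73)
  expect_equal(mean(shifted$scores[shifted$is_causal, 1]) -
                 mean(shifted$scores[!shifted$is_causal, 1]),
               1.5, tolerance = 0.15)
})

test_that("generation is reproducible from the seed", {
  a <- simulate_score_database(100, diag(1, 3), missing_rate = 0.1, seed = 74)
  b <- simulate_score_database(100, diag(1, 3), missing_rate = 0.1, seed = 74)
  expect_identical(a, b)
  w1 <- synthetic_world(seed = 3, n_loci = 4, n_diseases = 12)
  w2 <- synthetic_world(seed = 3, n_loci = 4, n_diseases = 12)
  expect_identical(w1$space, w2$space)
  expect_identical(as.character(w1$genome), as.character(w2$genome))
  c1 <- simulate_candidates(w1, "INTRON", 30, seed = 9)
  c2 <- simulate_candidates(w2, "INTRON", 30, seed = 9)
  expect_identical(c1, c2)
})

test_that("a null disease space yields uniform association p-values", {
  set.seed(75)
  ds <- simulate_disease_space(n_diseases = 30, slope = 0, seed = 76)
  p <- unlist(lapply(sprintf("G%02d", 2:20), function(g)
    gene_association_pvalues(g, ds$truth$query_disease, ds$space,
                             ds$measures[1])))
  p <- p[is.finite(p)]
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.001)
})

test_that("the planted causal gene shows stronger association than random genes", {
  set.seed(77)
  wins <- 0L
  for (s in 1:20) {
    ds <- simulate_disease_space(n_diseases = 40, slope = 0.15,
                                 noise_sd = 0.1, seed = 100 + s)
    pc <- min(gene_association_pvalues(ds$truth$causal_gene,
                                       ds$truth$query_disease,
                                       ds$space, ds$measures), na.rm = TRUE)
    pr <- min(gene_association_pvalues("G10", ds$truth$query_disease,
                                       ds$space, ds$measures), na.rm = TRUE)
    wins <- wins + (pc < pr)
  }
  expect_gte(wins, 15L)
})

test_that("spiked candidates classify into the requested region", {
  w <- synthetic_world(seed = 11, n_loci = 6, n_diseases = 12)
  for (reg in c("EXON", "PROMOTER", "INTRON", "SPLICE_SITE")) {
    cand <- simulate_candidates(w, reg, n_neutral = 20, seed = 13)
    expect_equal(nrow(cand$variants), 21L)
    expect_equal(sum(cand$variants$key == cand$causal_key), 1L)
    ann <- classify_variants(cand$variants, w$transcripts, w$genome)
    expect_true(all(ann$region == reg),
                info = paste(reg, toString(unique(ann$region))))
    causal_ann <- ann[ann$key == cand$causal_key, ]
    expect_equal(causal_ann$gene_id, w$truth$causal_gene)
  }
})

test_that("world artifacts round-trip through the package readers", {
  w <- synthetic_world(seed = 19, n_loci = 3, n_diseases = 10, n_null = 150)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  tx <- load_gene_models(file.path(dir, "genes.bed"))
  expect_length(tx, 3L)
  expect_equal(tx[[2]]$exon_starts, w$transcripts[[2]]$exon_starts)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(as.character(g[["chr1"]]), as.character(w$genome[["chr1"]]))
  phen <- read_similarity_matrix(file.path(dir, "phenotype_phen1.tsv"))
  expect_equal(phen, w$space$phenotype_sims$phen1, tolerance = 1e-9)
  dg <- read_disease_genes(file.path(dir, "disease_genes.tsv"),
                           diseases = w$space$diseases)
  expect_equal(lengths(dg), lengths(w$space$disease_genes))
  np <- read_null_panel(file.path(dir, "null_wgs1.txt"))
  expect_equal(np$values, w$null_panels$wgs1$values, tolerance = 1e-12)
  # score tables and VCF round-trip
  cand <- simulate_candidates(w, "PROMOTER", 15, seed = 3)
  stp <- file.path(dir, "scores.tsv")
  write_score_table(cand$variants[order(cand$variants$pos), ],
                    cand$score_table[match(cand$variants$key[order(cand$variants$pos)],
                                           cand$score_table$key), -1],
                    stp)
  st <- read_score_table(stp)
  expect_setequal(st$key, cand$score_table$key)
  vcf <- file.path(dir, "cand.vcf")
  write_snv_vcf(cand$variants, vcf)
  back <- read_snvs(vcf)
  expect_equal(back$n_skipped, 0)
  expect_setequal(back$variants$key, cand$variants$key)
})
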