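# Variant helper: single-row table at a 0-based position
v_at <- function(pos0, ref = "A", alt = "G", chrom = "chrT")
  genomic_variants(chrom, pos0 + 1L, ref, alt)

test_that("intronic offsets map to splice-site (1-2), intron (3-10), discard (>10)", {
  t <- list(toy_plus_transcript())  # intron [1100, 1200)
  # donor side: offset = pos0 - 1100 + 1
  expect_equal(classify_variant(v_at(1100L), t)$region, "SPLICE_SITE")
  expect_equal(classify_variant(v_at(1101L), t)$region, "SPLICE_SITE")
  expect_equal(classify_variant(v_at(1104L), t)$region, "INTRON")   # offset 5
  expect_equal(classify_variant(v_at(1109L), t)$region, "INTRON")   # offset 10
  expect_equal(classify_variant(v_at(1110L), t)$region, "DISCARD")  # offset 11
  expect_equal(classify_variant(v_at(1149L), t)$region, "DISCARD")  # offset 50
  # acceptor side mirrors
  expect_equal(classify_variant(v_at(1199L), t)$region, "SPLICE_SITE")
  expect_equal(classify_variant(v_at(1198L), t)$region, "SPLICE_SITE")
  expect_equal(classify_variant(v_at(1197L), t)$region, "INTRON")
  expect_equal(classify_variant(v_at(1190L), t)$region, "INTRON")   # offset 10
  expect_equal(classify_variant(v_at(1189L), t)$region, "DISCARD")
})

test_that("promoter window is 500 bp strand-aware upstream of the TSS", {
  t <- list(toy_plus_transcript())
  expect_equal(classify_variant(v_at(600L), t)$region, "PROMOTER")   # 400 up
  expect_equal(classify_variant(v_at(500L), t)$region, "PROMOTER")   # edge
  expect_equal(classify_variant(v_at(400L), t)$region, "DISCARD")    # 600 up
  expect_equal(classify_variant(v_at(1500L), t)$region, "DISCARD")   # downstream
  tm <- list(transcript_model("TOYM", "chrT", "-", 1000L, 1300L, 1000L, 1300L))
  expect_equal(classify_variant(v_at(1400L), tm)$region, "PROMOTER") # 100 past end
  expect_equal(classify_variant(v_at(1799L), tm)$region, "PROMOTER") # edge
  expect_equal(classify_variant(v_at(1800L), tm)$region, "DISCARD")
  expect_equal(classify_variant(v_at(900L), tm)$region, "DISCARD")   # downstream on -
})

test_that("UTRs classify as promoter and DISCARD implies empty gene", {
  t <- list(transcript_model("U", "chrT", "+", 1000L, 1300L,
                             cds_start = 1060L, cds_end = 1240L))
  a5 <- classify_variant(v_at(1010L), t)
  expect_equal(a5$region, "PROMOTER"); expect_equal(a5$detail, "utr5")
  a3 <- classify_variant(v_at(1250L), t)
  expect_equal(a3$region, "PROMOTER"); expect_equal(a3$detail, "utr3")
  d <- classify_variant(v_at(5000L), t)
  expect_equal(d$region, "DISCARD")
  expect_equal(d$gene_id, "")
})

test_that("codon substitutions translate correctly on both strands", {
  g <- codon_genome()
  fwd <- codon_plus_transcript()
  # ATG -> ATA: Met -> Ile, nonsynonymous
  ns <- is_nonsynonymous(genomic_variants("chrC", 13, "G", "A"), fwd, g)
  expect_true(ns$nonsynonymous)
  expect_equal(ns$detail, "M1I")
  # CTG -> TTG: Leu -> Leu, synonymous
  syn <- is_nonsynonymous(genomic_variants("chrC", 14, "C", "T"), fwd, g)
  expect_false(syn$nonsynonymous)
  expect_equal(syn$detail, "L2L")
  # minus strand: genomic C->T at pos0 36 maps to G->A on the transcript
  rev <- codon_minus_transcript()
  nsm <- is_nonsynonymous(genomic_variants("chrC", 37, "C", "T"), rev, g)
  expect_true(nsm$nonsynonymous)
  expect_equal(nsm$detail, "M1I")
  # reference mismatch is a data-integrity error
  expect_error(is_nonsynonymous(genomic_variants("chrC", 13, "C", "A"), fwd, g),
               "reference mismatch")
})

test_that("stop codon changes follow the count_stop toggle", {
  g <- codon_genome()
  fwd <- codon_plus_transcript()
  # GAA -> TAA: Glu -> stop
  v <- genomic_variants("chrC", 17, "G", "T")
  expect_true(is_nonsynonymous(v, fwd, g)$nonsynonymous)
  expect_false(is_nonsynonymous(v, fwd, g, count_stop = FALSE)$nonsynonymous)
})

test_that("synonymous CDS variants never classify as EXON (full codon enumeration)", {
  g <- codon_genome()
  tx <- list(codon_plus_transcript())
  # enumerate all 9 substitutions of codon 2 (CTG, pos0 13-15)
  for (off in 0:2) {
    pos0 <- 13L + off
    ref <- substr("CTG", off + 1L, off + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      a <- classify_variant(genomic_variants("chrC", pos0 + 1L, ref, alt),
                            tx, g)
      codon <- "CTG"; substr(codon, off + 1L, off + 1L) <- alt
      expected <- if (Biostrings::GENETIC_CODE[[codon]] ==
                      Biostrings::GENETIC_CODE[["CTG"]]) "DISCARD" else "EXON"
      expect_equal(a$region, expected,
                   info = sprintf("pos %d %s>%s", pos0, ref, alt))
    }
  }
})

test_that("classification is strand-symmetric under locus mirroring", {
  set.seed(42)
  w <- synthetic_world(seed = 5, n_loci = 2)
  L <- length(w$genome[[1]])
  mirror_genome <- Biostrings::DNAStringSet(
    Biostrings::reverseComplement(w$genome[[1]]))
  names(mirror_genome) <- "chr1"
  mirror_tx <- lapply(w$transcripts, function(t) {
    transcript_model(t$gene_id, "chr1",
                     if (t$strand == "+") "-" else "+",
                     rev(L - t$exon_ends), rev(L - t$exon_starts),
                     L - t$cds_end, L - t$cds_start)
  })
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (reg in c("EXON", "SPLICE_SITE", "INTRON", "PROMOTER")) {
    pool <- w$pools[[reg]]
    rows <- pool[sample(nrow(pool), 10), ]
    for (i in seq_len(10)) {
      pos0 <- rows$pos0[i]
      ref <- genome_fetch(w$genome, "chr1", pos0, pos0 + 1L)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      a <- classify_variant(genomic_variants("chr1", pos0 + 1L, ref, alt),
                            w$transcripts, w$genome)
      b <- classify_variant(
        genomic_variants("chr1", L - pos0, comp[[ref]], comp[[alt]]),
        mirror_tx, mirror_genome)
      expect_equal(b$region, a$region,
                   info = sprintf("%s pos0=%d", reg, pos0))
      expect_equal(b$gene_id, a$gene_id)
    }
  }
})

test_that("most severe class wins across transcripts and per-gene hits are kept", {
  g <- codon_genome()
  # overlapping genes: FWD's CDS position is also in an intron of a second gene
  t2 <- transcript_model("OVL", "chrC", "+", c(5L, 25L), c(10L, 35L), 5L, 10L)
  tx <- list(codon_plus_transcript(), t2)
  v <- genomic_variants("chrC", 13, "G", "A")  # EXON in FWD, intron offset 3 in OVL
  best <- classify_variant(v, tx, g)
  expect_equal(best$region, "EXON")
  expect_equal(best$gene_id, "FWD")
  all_hits <- classify_variants(v, tx, g, per_gene = TRUE)
  expect_equal(nrow(all_hits), 2L)
  expect_setequal(all_hits$gene_id, c("FWD", "OVL"))
  expect_equal(all_hits$region[all_hits$gene_id == "OVL"], "INTRON")
})
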