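# Shared toy fixtures, built in code.

# Plus-strand two-exon transcript: exons [1000,1100) and [1200,1300),
# CDS = exon union, TSS at 1000 (0-based half-open). Used for interval
# arithmetic; no genome needed.
toy_plus_transcript <- function() {
  transcript_model("TOY", "chrT", "+",
                   exon_starts = c(1000L, 1200L), exon_ends = c(1100L, 1300L),
                   cds_start = 1000L, cds_end = 1300L)
}

# Designed chromosome for codon tests:
#   pos0 10-18 (+ strand gene FWD): coding "ATG CTG GAA"
#   pos0 30-38 (- strand gene REV): genome "TTACTCCAT",
#     i.e. coding strand reads "ATGGAGTAA"
codon_genome <- function() {
  seq <- paste0(strrep("A", 10), "ATGCTGGAA",
                strrep("A", 11), "TTACTCCAT", strrep("A", 11))
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "chrC"
  g
}

codon_plus_transcript <- function() {
  transcript_model("FWD", "chrC", "+", 10L, 19L, 10L, 19L)
}

codon_minus_transcript <- function() {
  transcript_model("REV", "chrC", "-", 30L, 39L, 30L, 39L)
}

# Minimal disease space: 4 diseases, 1 phenotype measure
tiny_space <- function() {
  d <- c("d1", "d2", "d3", "d4")
  m <- matrix(0.5, 4, 4, dimnames = list(d, d)); diag(m) <- 1
  disease_space(list(phen = m),
                list(d1 = "gA", d2 = c("gB", "gC"), d3 = "gD",
                     d4 = character(0)))
}

tiny_phi <- function() {
  g <- c("gA", "gB", "gC", "gD", "gQ")
  m <- matrix(0.2, 5, 5, dimnames = list(g, g)); diag(m) <- 1
  m
}

# random regression inputs for oracle comparisons
random_regression_inputs <- function(n = 20, p = 3) {
  x <- stats::rnorm(n)
  Y <- matrix(stats::rnorm(n * p), n, p)
  list(Y = Y, x = x, row_ids = paste0("e", seq_len(n)))
}

# conservative competition rank of the causal variant under a
# single-source ranking (smaller p wins; ties and missingness count
# against the causal variant)
single_source_rank <- function(p, causal_idx) {
  p[!is.finite(p)] <- 2
  sum(p <= p[causal_idx])
}
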