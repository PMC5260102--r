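#' Load a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet` keyed by chromosome name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Fetch [start0, end0) from the genome (0-based half-open), as a character
# string on the + strand.
genome_fetch <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  as.character(Biostrings::subseq(genome[[chrom]], start = start0 + 1L, end = end0))
}
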