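#' Construct a table of SNVs
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (VCF convention).
#' @param ref,alt single reference/alternate nucleotides.
#' @param id optional identifiers (defaults to the variant key).
#' @return data.frame with columns `key, chrom, pos, ref, alt, id`.
#' @export
genomic_variants <- function(chrom, pos, ref, alt, id = NULL) {
  pos <- as.integer(pos)
  nt <- c("A", "C", "G", "T")
  if (any(pos < 1L)) stop("pos must be >= 1 (1-based VCF convention)")
  if (any(!ref %in% nt) || any(!alt %in% nt))
    stop("ref and alt must be single nucleotides in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  key <- variant_key(chrom, pos, ref, alt)
  data.frame(key = key, chrom = chrom, pos = pos, ref = ref, alt = alt,
             id = if (is.null(id)) key else id,
             stringsAsFactors = FALSE)
}

#' Variant key `chrom:pos:ref:alt`
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read candidate SNVs from a VCF
#'
#' Multi-allelic records are split into one row per alternate allele;
#' records that are not simple SNVs are skipped and counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @return list with `variants` (a [genomic_variants()] table) and
#'   `n_skipped` (non-SNV records dropped).
#' @export
read_snvs <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; id <- fix[, "ID"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n <- lengths(alts)
  chrom <- rep(chrom, n); pos <- rep(pos, n); ref <- rep(ref, n); id <- rep(id, n)
  alt <- unlist(alts)
  nt <- c("A", "C", "G", "T")
  ok <- ref %in% nt & alt %in% nt & ref != alt
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " non-SNV allele record(s) skipped")
  id <- ifelse(is.na(id) | id == ".", variant_key(chrom, pos, ref, alt), id)
  list(variants = genomic_variants(chrom[ok], pos[ok], ref[ok], alt[ok], id[ok]),
       n_skipped = n_skipped)
}

#' Write a minimal VCF for a table of SNVs
#'
#' @param variants a [genomic_variants()] table.
#' @param path output file.
#' @export
write_snv_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                       variants$chrom, variants$pos, variants$id,
                       variants$ref, variants$alt), con)
  invisible(path)
}
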