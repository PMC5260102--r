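# Region classification of SNVs against transcript models.
#
# Region definitions (all windows strand-aware, internal coordinates
# 0-based half-open):
#   EXON        nonsynonymous substitution within the CDS
#   SPLICE_SITE intronic offset 1-2 from the nearest exon/intron boundary
#   INTRON      intronic offset 3-10 from the nearest boundary
#   PROMOTER    within `promoter_window` bp upstream of the TSS, or a UTR
#   DISCARD     anything else (intergenic, deep intronic, synonymous CDS)
# Precedence when several transcripts/classes apply:
#   EXON > SPLICE_SITE > INTRON > PROMOTER (most severe wins).

REGION_LEVELS <- c("EXON", "SPLICE_SITE", "INTRON", "PROMOTER", "DISCARD")

#' Classify one SNV against a set of transcript models
#'
#' @param v single-row [genomic_variants()] table.
#' @param transcripts list of [transcript_model()].
#' @param genome reference genome from [read_genome()] (needed for the
#'   nonsynonymous test; may be `NULL` if no transcript has a CDS).
#' @param promoter_window bp upstream of the TSS counted as promoter.
#' @param count_stop treat stop-gain/stop-loss as nonsynonymous.
#' @return list with `region` (EXON, SPLICE_SITE, INTRON, PROMOTER or
#'   DISCARD), `gene_id` (`""` when DISCARD) and `detail`.
#' @export
classify_variant <- function(v, transcripts, genome = NULL,
                             promoter_window = 500L, count_stop = TRUE) {
  as.list(classify_variants(v, transcripts, genome, promoter_window,
                            count_stop)[1, c("region", "gene_id", "detail")])
}

#' Classify a table of SNVs
#'
#' Vectorised form of [classify_variant()]; CDS sequences are extracted
#' once per transcript. With `per_gene = TRUE` every (variant, gene)
#' assignment is returned (one row per host gene, each gene's most
#' severe class); otherwise the single most severe assignment per
#' variant, ties between genes broken lexicographically.
#'
#' @inheritParams classify_variant
#' @param variants a [genomic_variants()] table.
#' @param per_gene return all per-gene assignments instead of the best.
#' @return data.frame with columns `key, region, gene_id, detail`.
#' @export
classify_variants <- function(variants, transcripts, genome = NULL,
                              promoter_window = 500L, count_stop = TRUE,
                              per_gene = FALSE) {
  ctx <- lapply(transcripts, function(t) {
    if (t$cds_end > t$cds_start && !is.null(genome) && t$chrom %in% names(genome))
      cds_context(t, genome) else NULL
  })
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    hits <- list()
    for (j in seq_along(transcripts)) {
      t <- transcripts[[j]]
      if (t$chrom != variants$chrom[i]) next
      a <- classify_against_transcript(variants$pos[i] - 1L, variants$ref[i],
                                       variants$alt[i], t, ctx[[j]],
                                       promoter_window, count_stop)
      if (a$region == "DISCARD") next
      cur <- hits[[t$gene_id]]
      if (is.null(cur) ||
          match(a$region, REGION_LEVELS) < match(cur$region, REGION_LEVELS))
        hits[[t$gene_id]] <- a
    }
    if (!length(hits)) {
      rows[[i]] <- data.frame(key = variants$key[i], region = "DISCARD",
                              gene_id = "", detail = "", stringsAsFactors = FALSE)
      next
    }
    genes <- sort(names(hits))
    df <- data.frame(key = variants$key[i],
                     region = vapply(hits[genes], `[[`, "", "region"),
                     gene_id = genes,
                     detail = vapply(hits[genes], `[[`, "", "detail"),
                     stringsAsFactors = FALSE, row.names = NULL)
    if (!per_gene)
      df <- df[order(match(df$region, REGION_LEVELS), df$gene_id)[1L], , drop = FALSE]
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

classify_against_transcript <- function(pos0, ref, alt, t, ctx,
                                        promoter_window, count_stop) {
  none <- list(region = "DISCARD", gene_id = "", detail = "")
  in_exon <- any(pos0 >= t$exon_starts & pos0 < t$exon_ends)
  if (in_exon && pos0 >= t$cds_start && pos0 < t$cds_end) {
    if (is.null(ctx)) return(none)
    ns <- is_nonsynonymous_ctx(pos0, ref, alt, t, ctx, count_stop)
    if (ns$nonsynonymous)
      return(list(region = "EXON", gene_id = t$gene_id, detail = ns$detail))
    # synonymous CDS change: no class from this transcript
    return(none)
  }
  intr <- transcript_introns(t)
  for (k in seq_len(nrow(intr))) {
    s <- intr[k, "start"]; e <- intr[k, "end"]
    if (pos0 >= s && pos0 < e) {
      offset <- min(pos0 - s + 1L, e - pos0)  # distance into intron from nearest boundary
      if (offset <= 2L)
        return(list(region = "SPLICE_SITE", gene_id = t$gene_id,
                    detail = paste0("intron_offset=", offset)))
      if (offset <= 10L)
        return(list(region = "INTRON", gene_id = t$gene_id,
                    detail = paste0("intron_offset=", offset)))
      return(none)  # deep intronic
    }
  }
  up <- if (t$strand == "+") {
    pos0 >= t$tss - promoter_window && pos0 < t$tss
  } else {
    pos0 >= t$tss && pos0 < t$tss + promoter_window
  }
  if (up)
    return(list(region = "PROMOTER", gene_id = t$gene_id, detail = "upstream"))
  if (in_exon) {
    utr <- transcript_utrs(t)
    for (side in c("utr5", "utr3")) {
      iv <- utr[[side]]
      if (nrow(iv) && any(pos0 >= iv[, "start"] & pos0 < iv[, "end"]))
        return(list(region = "PROMOTER", gene_id = t$gene_id, detail = side))
    }
  }
  none
}

# CDS sequence and the genomic position of each CDS base (+ strand order)
cds_context <- function(t, genome) {
  s <- pmax(t$exon_starts, t$cds_start)
  e <- pmin(t$exon_ends, t$cds_end)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  seq <- paste0(vapply(seq_along(s), function(i)
    genome_fetch(genome, t$chrom, s[i], e[i]), character(1)), collapse = "")
  gpos <- unlist(lapply(seq_along(s), function(i) seq.int(s[i], e[i] - 1L)))
  list(seq = seq, gpos = gpos)
}

#' Test whether a CDS substitution is nonsynonymous
#'
#' The codon containing the variant is read off the coding sequence
#' (reverse-complemented for minus-strand transcripts), the alternate
#' allele substituted, and both codons translated with the standard
#' genetic code.
#'
#' @inheritParams classify_variant
#' @param t a coding [transcript_model()] containing the variant position.
#' @return list with `nonsynonymous` (logical) and `detail`
#'   (e.g. `"M1I"` for Met1Ile).
#' @export
is_nonsynonymous <- function(v, t, genome, count_stop = TRUE) {
  ctx <- cds_context(t, genome)
  is_nonsynonymous_ctx(v$pos - 1L, v$ref, v$alt, t, ctx, count_stop)
}

is_nonsynonymous_ctx <- function(pos0, ref, alt, t, ctx, count_stop) {
  i <- match(pos0, ctx$gpos)
  if (is.na(i)) stop("position ", pos0 + 1L, " not inside the CDS of ", t$gene_id)
  gref <- substr(ctx$seq, i, i)
  if (gref != ref)
    stop("reference mismatch at ", t$chrom, ":", pos0 + 1L,
         ": genome has ", gref, ", variant claims ", ref)
  L <- nchar(ctx$seq)
  if (L %% 3L != 0L)
    warning("CDS length of ", t$gene_id, " not divisible by 3; using local codon")
  if (t$strand == "+") {
    p <- i - 1L                     # 0-based position on the coding strand
    cds <- ctx$seq
    sub_base <- alt
  } else {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctx$seq)))
    p <- L - i                      # 0-based on the reverse complement
    sub_base <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  }
  codon_idx <- p %/% 3L
  within <- p %% 3L
  cstart <- codon_idx * 3L + 1L
  if (cstart + 2L > L)
    return(list(nonsynonymous = FALSE, detail = "incomplete_codon"))
  codon <- substr(cds, cstart, cstart + 2L)
  alt_codon <- codon
  substr(alt_codon, within + 1L, within + 1L) <- sub_base
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  changed <- aa_ref != aa_alt
  if (!count_stop && (aa_ref == "*" || aa_alt == "*")) changed <- FALSE
  list(nonsynonymous = changed,
       detail = paste0(aa_ref, codon_idx + 1L, aa_alt))
}
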