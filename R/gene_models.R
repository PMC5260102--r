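#' Construct a transcript model
#'
#' A transcript model holds the coordinates needed for region
#' classification: exon structure, CDS bounds and the strand-aware
#' transcription start site (TSS). All internal coordinates are 0-based,
#' half-open; VCF positions (1-based) are converted on read.
#'
#' @param gene_id gene identifier the transcript belongs to.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of 0-based half-open exon
#'   intervals, sorted and non-overlapping.
#' @param cds_start,cds_end 0-based half-open CDS bounds (within the exon
#'   union). Equal values denote a noncoding transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                             cds_start = exon_starts[1], cds_end = exon_starts[1]) {
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) == 0L)
    stop("exon_starts and exon_ends must be equal-length, non-empty")
  if (any(exon_ends <= exon_starts))
    stop("exons must be non-empty half-open intervals")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (length(exon_starts) > 1L && any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("exons overlap")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end < cds_start) stop("cds_end < cds_start")
  t <- structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exon_starts = exon_starts, exon_ends = exon_ends,
    cds_start = cds_start, cds_end = cds_end
  ), class = "transcript_model")
  t$tss <- if (strand == "+") exon_starts[1L] else exon_ends[length(exon_ends)]
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s%s) %d exon(s), CDS [%d,%d), TSS %d\n",
              x$gene_id, x$chrom, x$strand, length(x$exon_starts),
              x$cds_start, x$cds_end, x$tss))
  invisible(x)
}

# 0-based half-open intron intervals between consecutive exons
transcript_introns <- function(t) {
  k <- length(t$exon_starts)
  if (k < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = t$exon_ends[-k], end = t$exon_starts[-1L])
}

# exonic intervals outside the CDS, split into 5' and 3' by strand
transcript_utrs <- function(t) {
  clip <- function(lo, hi) {
    s <- pmax(t$exon_starts, lo); e <- pmin(t$exon_ends, hi)
    keep <- e > s
    cbind(start = s[keep], end = e[keep])
  }
  left <- clip(-.Machine$integer.max, t$cds_start)
  right <- clip(t$cds_end, .Machine$integer.max)
  if (t$strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Load gene models from BED12 or GFF3
#'
#' Reads transcript records through `rtracklayer` and converts them to
#' [transcript_model()] objects (0-based half-open internal coordinates).
#' For BED12 the thickStart/thickEnd fields give the CDS; for GFF3 the
#' union of `exon` children and the span of `CDS` children of each
#' transcript (grouped by `Parent`, falling back to `ID`) are used, with
#' `gene_id`/`Parent` of the transcript naming the host gene.
#'
#' @param path file path; dialect guessed from the extension unless given.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return list of `transcript_model`.
#' @export
load_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") load_gene_models_bed(path) else load_gene_models_gff3(path)
}

load_gene_models_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop("BED12 parse error at line ", i, ": expected 12 fields, found ", length(f))
    if (!f[6L] %in% c("+", "-"))
      stop("invalid strand '", f[6L], "' at line ", i)
  }
  gr <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(gr), function(i) {
    g <- gr[i]
    blocks <- IRanges::shift(unlist(g$blocks), GenomicRanges::start(g) - 1L)
    transcript_model(
      gene_id = g$name, chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      exon_starts = GenomicRanges::start(blocks) - 1L,
      exon_ends = GenomicRanges::end(blocks),
      cds_start = GenomicRanges::start(g$thick) - 1L,
      cds_end = GenomicRanges::end(g$thick)
    )
  })
}

load_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  feat <- as.character(gr$type)
  parent_of <- function(g) {
    p <- g$Parent
    if (!is.null(p) && length(p) && length(p[[1L]])) as.character(p[[1L]][1L]) else NA_character_
  }
  ex <- gr[feat == "exon"]; cds <- gr[feat == "CDS"]
  tx_ids <- unique(vapply(seq_along(ex), function(i) parent_of(ex[i]), character(1)))
  tx_ids <- tx_ids[!is.na(tx_ids)]
  tx <- gr[!is.na(gr$ID) & as.character(gr$ID) %in% tx_ids]
  lapply(tx_ids, function(id) {
    e <- ex[vapply(seq_along(ex), function(i) identical(parent_of(ex[i]), id), logical(1))]
    cc <- cds[vapply(seq_along(cds), function(i) identical(parent_of(cds[i]), id), logical(1))]
    rec <- tx[as.character(tx$ID) == id]
    gene <- if (length(rec)) {
      p <- parent_of(rec[1]); if (is.na(p)) id else p
    } else id
    strand <- as.character(GenomicRanges::strand(e))[1L]
    if (!strand %in% c("+", "-")) stop("invalid strand '", strand, "' for transcript ", id)
    cs <- if (length(cc)) min(GenomicRanges::start(cc)) - 1L else GenomicRanges::start(e)[1L] - 1L
    ce <- if (length(cc)) max(GenomicRanges::end(cc)) else GenomicRanges::start(e)[1L] - 1L
    transcript_model(
      gene_id = gene, chrom = as.character(GenomicRanges::seqnames(e))[1L],
      strand = strand,
      exon_starts = GenomicRanges::start(e) - 1L, exon_ends = GenomicRanges::end(e),
      cds_start = cs, cds_end = ce
    )
  })
}
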