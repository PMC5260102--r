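# Plain-text readers/writers for the pipeline's tabular inputs. All
# tables are tab-separated with a header; "." marks a missing value.

#' Read a per-variant score table
#'
#' Expected header: `chrom pos ref alt` followed by one column per
#' score; `.` denotes a missing score.
#'
#' @param path TSV file.
#' @return data.frame with a derived `key` column plus the score columns.
#' @export
read_score_table <- function(path) {
  d <- utils::read.delim(path, na.strings = ".", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d)))
    stop("score table must have columns ", paste(need, collapse = ", "))
  cbind(data.frame(key = variant_key(d$chrom, d$pos, d$ref, d$alt),
                   stringsAsFactors = FALSE),
        d[setdiff(names(d), need)])
}

#' Write a per-variant score table
#'
#' @param variants [genomic_variants()] table aligned with `scores`.
#' @param scores data.frame/matrix of score columns (NA for missing).
#' @param path output TSV.
#' @export
write_score_table <- function(variants, scores, path) {
  d <- cbind(variants[c("chrom", "pos", "ref", "alt")], as.data.frame(scores))
  utils::write.table(d, path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a symmetric similarity matrix (TSV with row and column names)
#' @param path TSV file.
#' @export
read_similarity_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("similarity matrix in ", path, " is not symmetric")
  m
}

#' Write a similarity matrix as TSV
#' @param m matrix with dimnames.
#' @param path output TSV.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.table(cbind(id = rownames(m), format(as.data.frame(m), digits = 15)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-to-gene association table (columns `disease`, `gene`)
#'
#' @param path TSV file.
#' @param diseases optional disease ids to include even when geneless.
#' @return named list disease -> character vector of genes.
#' @export
read_disease_genes <- function(path, diseases = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  sets <- split(d$gene, d$disease)
  if (!is.null(diseases)) {
    missing <- setdiff(diseases, names(sets))
    sets <- c(sets, stats::setNames(rep(list(character(0)), length(missing)),
                                    missing))
    sets <- sets[diseases]
  }
  sets
}

#' Write a disease-to-gene association table
#' @param disease_genes named list disease -> genes.
#' @param path output TSV.
#' @export
write_disease_genes <- function(disease_genes, path) {
  d <- data.frame(disease = rep(names(disease_genes), lengths(disease_genes)),
                  gene = unlist(disease_genes, use.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an empirical null panel (one value per line + JSON sidecar)
#' @param null a [build_empirical_null()] panel.
#' @param path output file; the sidecar is `<path>.json`.
#' @export
write_null_panel <- function(null, path) {
  writeLines(format(null$values, digits = 17, trim = TRUE, scientific = FALSE), path)
  jsonlite::write_json(list(score_name = null$score_name, n = null$n),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an empirical null panel written by [write_null_panel()]
#' @param path panel file.
#' @export
read_null_panel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  values <- as.numeric(readLines(path))
  if (length(values) != meta$n)
    stop("null panel ", path, ": expected ", meta$n, " values, found ",
         length(values))
  build_empirical_null(values, score_name = meta$score_name,
                       min_n = min(meta$n, 100L))
}

#' Write toy gene models as BED12
#' @param transcripts list of [transcript_model()].
#' @param path output BED file.
#' @export
write_gene_models_bed <- function(transcripts, path) {
  lines <- vapply(transcripts, function(t) {
    k <- length(t$exon_starts)
    paste(t$chrom, t$exon_starts[1], t$exon_ends[k], t$gene_id, 0, t$strand,
          t$cds_start, t$cds_end, "0",
          k, paste0(paste(t$exon_ends - t$exon_starts, collapse = ","), ","),
          paste0(paste(t$exon_starts - t$exon_starts[1], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic world to a directory of plain-text artifacts
#'
#' Emits `genome.fa`, `genes.bed`, `phenotype_<m>.tsv`,
#' `gene_sim_<m>.tsv`, `disease_genes.tsv`, `null_<score>.txt(.json)`,
#' `scores.yaml` (score configuration) and `truth.json`.
#'
#' @param world a [synthetic_world()].
#' @param dir output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(world$genome, p("genome.fa"))
  write_gene_models_bed(world$transcripts, p("genes.bed"))
  for (m in names(world$space$phenotype_sims))
    write_similarity_matrix(world$space$phenotype_sims[[m]],
                            p(sprintf("phenotype_%s.tsv", m)))
  for (m in names(world$gene_measures))
    write_similarity_matrix(world$gene_measures[[m]],
                            p(sprintf("gene_sim_%s.tsv", m)))
  write_disease_genes(world$space$disease_genes, p("disease_genes.tsv"))
  for (s in names(world$null_panels))
    write_null_panel(world$null_panels[[s]], p(sprintf("null_%s.txt", s)))
  yaml::write_yaml(list(scores = world$score_defs$name,
                        direction = world$score_defs$direction,
                        regions = world$score_defs$regions,
                        neutral_genes = world$neutral_genes,
                        query_disease = world$truth$query_disease),
                   p("scores.yaml"))
  jsonlite::write_json(world$truth, p("truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
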