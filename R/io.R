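#' Read / write interval tables as BED
#'
#' Plain BED6 (or BED3) via rtracklayer; coordinates are converted to the
#' package's 0-based half-open convention (which is BED's own, so the files
#' round-trip byte-exactly at the coordinate level).
#'
#' @param path file path.
#' @return Interval data.frame (with a \code{name} column when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  if (!is.null(gr$name)) df$name <- gr$name
  df
}

#' @rdname read_bed
#' @param x interval data.frame.
#' @export
write_bed <- function(x, path) {
  strand <- x$strand
  strand[is.null(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end),
                               strand = strand)
  if (!is.null(x$name)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write called peaks (BED6+3 dialect)
#'
#' Columns: chrom, start, end, name, score (-log10 q), strand, then
#' fold_enrichment, p_value, q_value. Tab-separated, no header.
#'
#' @param path file path.
#' @return Peak data.frame.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "fold_enrichment",
                                        "p_value", "q_value"))
  df$summit_offset <- NA_integer_
  validate_intervals(df)
  df
}

#' @rdname read_peaks
#' @param peaks peak data.frame from [call_peaks()].
#' @export
write_peaks <- function(peaks, path) {
  score <- round(-log10(pmax(peaks$q_value, 1e-300)), 3)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    paste0("peak_", seq_len(nrow(peaks))), score,
                    peaks$strand, signif(peaks$fold_enrichment, 6),
                    signif(peaks$p_value, 6), signif(peaks$q_value, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a genome table (two-column TSV: chrom, length)
#' @param path file path.
#' @return Named numeric vector (see [genome_table()]).
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  genome_table(df$chrom, df$length)
}

#' @rdname read_genome_table
#' @param genome named length vector.
#' @export
write_genome_table <- function(genome, path) {
  utils::write.table(data.frame(names(genome), as.integer(genome)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write gene models in the packaged TSV dialect
#'
#' One row per gene with header: gene_id, chrom, strand, exon_starts,
#' exon_ends (comma-separated), cds_start, cds_end, biotype.
#'
#' @param path file path.
#' @return Gene-model data.frame.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(exon_starts = "character",
                                         exon_ends = "character"))
  validate_gene_models(df)
  df
}

#' @rdname read_gene_models
#' @param genes gene-model data.frame.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write TE annotation (BED + class/family/full_length columns)
#' @param path file path.
#' @return TE annotation data.frame.
#' @export
read_te_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "strand",
                                        "te_class", "te_family", "full_length"))
  te_annotation(df$chrom, df$start, df$end, df$strand,
                df$te_class, df$te_family, as.logical(df$full_length))
}

#' @rdname read_te_annotation
#' @param te TE annotation data.frame.
#' @export
write_te_annotation <- function(te, path) {
  utils::write.table(te[, c("chrom", "start", "end", "strand", "te_class",
                            "te_family", "full_length")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene set (one id per line)
#' @param path file path.
#' @return Character vector of ids (blank lines and duplicates dropped).
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  unique(trimws(ids[nzchar(trimws(ids))]))
}

#' Read decay time courses (TSV: gene, condition, time_h, rel_expr)
#' @param path file path.
#' @return data.frame consumable by [fit_decay_table()].
#' @export
read_decay_courses <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "condition", "time_h", "rel_expr") %in% names(df)))
  df
}

#' Read an expression matrix (TSV with gene ids in the first column)
#'
#' Sample conditions are taken from column names of the form
#' \code{<condition>_<replicate>}.
#'
#' @param path file path.
#' @return List with \code{counts} (numeric matrix) and \code{conditions}.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  list(counts = m, conditions = sub("_[^_]*$", "", colnames(m)))
}

#' Read gene models from GTF-like exon/CDS rows
#'
#' Accepts a minimal GTF-style table (1-based closed coordinates, converted
#' on read): columns chrom, source, feature, start, end, score, strand,
#' frame, attributes with \code{gene_id "..."} in the attributes. Exon rows
#' define the exon structure; CDS rows (if any) are unioned into the CDS
#' span and set biotype to coding.
#'
#' @param path file path.
#' @return Gene-model data.frame in the package's 0-based convention.
#' @export
read_gtf_genes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#",
                          col.names = c("chrom", "source", "feature", "start",
                                        "end", "score", "strand", "frame",
                                        "attributes"))
  gid <- sub('.*gene_id[ =]*"?([^";]+)"?.*', "\\1", df$attributes)
  out <- lapply(split(seq_len(nrow(df)), gid), function(idx) {
    d <- df[idx, , drop = FALSE]
    ex <- d[d$feature == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cdsr <- d[d$feature == "CDS", , drop = FALSE]
    data.frame(gene_id = gid[idx[1]], chrom = d$chrom[1], strand = d$strand[1],
               exon_starts = paste(ex$start - 1L, collapse = ","),
               exon_ends = paste(ex$end, collapse = ","),
               cds_start = if (nrow(cdsr)) min(cdsr$start) - 1L else NA_integer_,
               cds_end = if (nrow(cdsr)) max(cdsr$end) else NA_integer_,
               biotype = if (nrow(cdsr)) "coding" else "noncoding",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_gene_models(res)
  res
}
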