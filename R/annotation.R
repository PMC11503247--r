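#' Gene models
#'
#' A gene model table has one row per gene: \code{gene_id}, \code{chrom},
#' \code{strand}, comma-separated \code{exon_starts} / \code{exon_ends}
#' (0-based half-open, sorted, pairwise disjoint), \code{cds_start},
#' \code{cds_end} (genomic; \code{NA} for noncoding genes) and \code{biotype}
#' (\code{"coding"} or \code{"noncoding"}). For coding genes the CDS must lie
#' within the exonic span and span at least 3 bp, so that a stop-codon
#' interval of exactly 3 bp can be derived.
#'
#' @param gene_id,chrom,strand character vectors.
#' @param exon_starts,exon_ends lists of integer vectors, or comma-separated
#'   strings.
#' @param cds_start,cds_end genomic CDS bounds (NA for noncoding).
#' @param biotype \code{"coding"} or \code{"noncoding"}.
#' @return Validated gene-model \code{data.frame}.
#' @export
gene_models <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                        cds_start = NA, cds_end = NA, biotype = "coding") {
  pack <- function(x) {
    if (is.list(x)) vapply(x, function(v) paste(as.integer(v), collapse = ","),
                           character(1))
    else as.character(x)
  }
  n <- length(gene_id)
  rec <- function(x) rep(x, length.out = n)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = rec(as.character(chrom)),
                   strand = rec(as.character(strand)),
                   exon_starts = rec(pack(exon_starts)),
                   exon_ends = rec(pack(exon_ends)),
                   cds_start = rec(as.integer(cds_start)),
                   cds_end = rec(as.integer(cds_end)),
                   biotype = rec(as.character(biotype)),
                   stringsAsFactors = FALSE)
  validate_gene_models(df)
  df
}

.unpack <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

#' @rdname gene_models
#' @param genes a gene-model data.frame.
#' @export
validate_gene_models <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    es <- .unpack(genes$exon_starts[i]); ee <- .unpack(genes$exon_ends[i])
    if (length(es) != length(ee) || any(es >= ee))
      stop("malformed exons for gene ", genes$gene_id[i], call. = FALSE)
    if (is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)]))
      stop("exons must be sorted and pairwise disjoint for gene ",
           genes$gene_id[i], call. = FALSE)
    if (identical(genes$biotype[i], "coding")) {
      cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
      if (is.na(cs) || is.na(ce) || ce - cs < 3)
        stop("coding gene ", genes$gene_id[i], " needs a CDS of >= 3 bp",
             call. = FALSE)
      if (cs < min(es) || ce > max(ee))
        stop("annotation inconsistency: CDS outside exonic span for gene ",
             genes$gene_id[i], call. = FALSE)
    }
  }
  invisible(genes)
}

#' Exons of a gene-model table as an interval table
#'
#' @param genes gene-model data.frame.
#' @return Interval data.frame with a \code{gene_id} column.
#' @export
gene_exons <- function(genes) {
  if (nrow(genes) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0),
                             gene_id = character(0)))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    es <- .unpack(genes$exon_starts[i]); ee <- .unpack(genes$exon_ends[i])
    data.frame(chrom = genes$chrom[i], start = es, end = ee,
               strand = genes$strand[i], gene_id = genes$gene_id[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic span of each gene (first exon start to last exon end)
#' @param genes gene-model data.frame.
#' @return Interval data.frame with \code{gene_id}.
#' @export
gene_spans <- function(genes) {
  ex <- gene_exons(genes)
  if (nrow(ex) == 0) return(ex)
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1], gene_id = d$gene_id[1],
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Stop-codon interval of coding genes
#'
#' The stop codon is the final 3 coding bases: \code{[cds_end - 3, cds_end)}
#' on the plus strand, \code{[cds_start, cds_start + 3)} on the minus strand.
#' Always exactly 3 bp.
#'
#' @param genes gene-model data.frame.
#' @return Interval data.frame with \code{gene_id}, one row per coding gene.
#' @export
stop_codon_intervals <- function(genes) {
  g <- genes[genes$biotype == "coding", , drop = FALSE]
  if (nrow(g) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0),
                             gene_id = character(0)))
  st <- ifelse(g$strand == "-", g$cds_start, g$cds_end - 3L)
  genomic_intervals(g$chrom, st, st + 3L, g$strand, gene_id = g$gene_id)
}

.clip_to_genome <- function(df, genome) {
  if (nrow(df) == 0) return(df)
  df$start <- pmax(df$start, 0L)
  df$end <- pmin(df$end, as.integer(genome[df$chrom]))
  df[df$start < df$end, , drop = FALSE]
}

#' Derive gene-feature interval sets
#'
#' Partitions the genome into the feature classes used for peak enrichment:
#' TSS windows, 5'UTR, CDS, stop-codon windows, 3'UTR, intron and intergenic.
#' Exonic bases of coding genes are partitioned exactly into UTR5/CDS/UTR3 by
#' the CDS bounds (strand-aware); intron is the intra-gene non-exonic space;
#' intergenic is the genome complement of gene spans and TSS windows. All
#' windows are clipped to chromosome bounds.
#'
#' @param genes gene-model data.frame.
#' @param genome genome table.
#' @param tss_flank half-width in bp of the TSS window (default 100).
#' @param stop_flank flank in bp around the 3-bp stop codon (default 200, so
#'   the stop-codon window spans 403 bp).
#' @return Named list of interval data.frames:
#'   \code{TSS, UTR5, CDS, stop_codon, UTR3, intron, intergenic}.
#' @export
derive_features <- function(genes, genome, tss_flank = 100, stop_flank = 200) {
  stopifnot(tss_flank >= 0, stop_flank >= 0)
  validate_gene_models(genes)
  empty <- genomic_intervals(character(0), integer(0), integer(0))
  utr5 <- utr3 <- cds <- intron <- list()
  tss <- list()
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; strand <- genes$strand[i]
    es <- .unpack(genes$exon_starts[i]); ee <- .unpack(genes$exon_ends[i])
    tss_pos <- if (strand == "-") max(ee) else min(es)
    tss[[i]] <- data.frame(chrom = ch, start = tss_pos - tss_flank,
                           end = tss_pos + tss_flank, strand = strand,
                           stringsAsFactors = FALSE)
    ## intron = gene span minus exons
    span_ir <- IRanges::IRanges(min(es) + 1L, max(ee))
    ex_ir <- IRanges::IRanges(es + 1L, ee)
    intr <- IRanges::setdiff(span_ir, ex_ir)
    if (length(intr) > 0) intron[[length(intron) + 1L]] <-
      .from_iranges(intr, ch, strand)
    if (genes$biotype[i] != "coding") next
    cs <- genes$cds_start[i]; ce <- genes$cds_end[i]
    left <- IRanges::restrict(ex_ir, end = cs)        # exonic bases < cds_start
    mid <- IRanges::restrict(ex_ir, start = cs + 1L, end = ce)
    right <- IRanges::restrict(ex_ir, start = ce + 1L)
    if (length(mid) > 0) cds[[length(cds) + 1L]] <- .from_iranges(mid, ch, strand)
    if (strand == "-") { u5 <- right; u3 <- left } else { u5 <- left; u3 <- right }
    if (length(u5) > 0) utr5[[length(utr5) + 1L]] <- .from_iranges(u5, ch, strand)
    if (length(u3) > 0) utr3[[length(utr3) + 1L]] <- .from_iranges(u3, ch, strand)
  }
  bindf <- function(lst) if (length(lst)) do.call(rbind, lst) else empty
  stop3 <- stop_codon_intervals(genes)
  stopw <- stop3
  if (nrow(stopw) > 0) {
    stopw$start <- stopw$start - as.integer(stop_flank)
    stopw$end <- stopw$end + as.integer(stop_flank)
  }
  spans <- gene_spans(genes)
  tssdf <- bindf(tss)
  occupied <- rbind(spans[, c("chrom", "start", "end", "strand")],
                    if (nrow(tssdf)) .clip_to_genome(tssdf, genome)[
                      , c("chrom", "start", "end", "strand")] else NULL)
  feats <- list(TSS = tssdf, UTR5 = bindf(utr5), CDS = bindf(cds),
                stop_codon = stopw[, c("chrom", "start", "end", "strand")],
                UTR3 = bindf(utr3), intron = bindf(intron),
                intergenic = .complement_intervals(
                  if (is.null(occupied)) empty else occupied, genome))
  lapply(feats, function(f) {
    f <- .clip_to_genome(f, genome)
    rownames(f) <- NULL
    f
  })
}

#' Transposable-element annotation
#'
#' TE copies are interval rows with \code{te_class} drawn from the four-class
#' repeat taxonomy (DNA, SINE, LINE, LTR), a \code{te_family} (e.g. MERVL,
#' L1) and a \code{full_length} flag used for metagene profiles over
#' full-length MERVL copies.
#'
#' @param chrom,start,end,strand interval columns.
#' @param te_class one of DNA, SINE, LINE, LTR.
#' @param te_family family name string.
#' @param full_length logical.
#' @return Validated TE annotation data.frame.
#' @export
te_annotation <- function(chrom, start, end, strand = ".",
                          te_class, te_family, full_length = FALSE) {
  df <- genomic_intervals(chrom, start, end, strand,
                          te_class = as.character(te_class),
                          te_family = as.character(te_family),
                          full_length = as.logical(full_length))
  if (!all(df$te_class %in% c("DNA", "SINE", "LINE", "LTR")))
    stop("te_class must be one of DNA, SINE, LINE, LTR", call. = FALSE)
  df
}

#' Group TE copies into feature sets by class or family
#'
#' At the class level the four repeat classes each form a feature set; at the
#' family level the universe is restricted to LINE and LTR families.
#'
#' @param te TE annotation data.frame.
#' @param level \code{"class"} or \code{"family"}.
#' @return Named list of interval data.frames.
#' @export
te_feature_sets <- function(te, level = c("class", "family")) {
  level <- match.arg(level)
  if (level == "class") {
    split(te[, c("chrom", "start", "end", "strand")], te$te_class)
  } else {
    te <- te[te$te_class %in% c("LINE", "LTR"), , drop = FALSE]
    split(te[, c("chrom", "start", "end", "strand")], te$te_family)
  }
}
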