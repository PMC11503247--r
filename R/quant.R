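#' Per-gene m6A status from called peaks
#'
#' A gene is m6A-positive iff at least one peak has more than half of its
#' length inside the union of the gene's exons and its stop-codon window
#' (stop codon +/- \code{stop_flank} bp) — the same > 50%-of-peak rule used
#' in the enrichment counting.
#'
#' @param peaks interval data.frame.
#' @param genes gene-model data.frame.
#' @param stop_flank flank around the stop codon included in the gene region
#'   (default 200 bp).
#' @param condition condition tag stored in the output.
#' @return data.frame: gene_id, condition, status (logical), n_peaks.
#' @export
gene_m6a_status <- function(peaks, genes, stop_flank = 200,
                            condition = "NA") {
  ex <- gene_exons(genes)
  stopw <- stop_codon_intervals(genes)
  if (nrow(stopw) > 0) {
    stopw$start <- pmax(stopw$start - as.integer(stop_flank), 0L)
    stopw$end <- stopw$end + as.integer(stop_flank)
  }
  n_peaks <- integer(nrow(genes))
  if (nrow(peaks) > 0) {
    plen <- peaks$end - peaks$start
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      region <- rbind(ex[ex$gene_id == gid, c("chrom", "start", "end", "strand")],
                      stopw[stopw$gene_id == gid,
                            c("chrom", "start", "end", "strand")])
      ov <- .overlap_bp_with_set(peaks, region)
      n_peaks[i] <- sum(ov / plen > 0.5)
    }
  }
  data.frame(gene_id = genes$gene_id, condition = condition,
             status = n_peaks >= 1L, n_peaks = n_peaks,
             stringsAsFactors = FALSE)
}

#' Per-gene m6A signal intensity
#'
#' Intensity is \code{log2((IP RPM + 1) / (input RPM + 1))} summed over a
#' per-gene region: either the stop codon +/- 200 bp window
#' (\code{region = "stop200"}) or the union of the gene's assigned peaks
#' (\code{region = "peaks"}, requires \code{peaks}). Regions outside
#' chromosome bounds are clipped with a warning. Invariant under equal
#' scaling of both library sizes.
#'
#' @param ip,input \code{coverage_track}s.
#' @param genes gene-model data.frame.
#' @param region \code{"stop200"} or \code{"peaks"}.
#' @param peaks peak data.frame (needed for \code{region = "peaks"}).
#' @param stop_flank flank for the stop-codon region mode (default 200).
#' @param genome genome table for bound clipping (optional).
#' @return data.frame: gene_id, intensity, region.
#' @export
m6a_intensity <- function(ip, input, genes, region = c("stop200", "peaks"),
                          peaks = NULL, stop_flank = 200, genome = NULL) {
  region <- match.arg(region)
  .check_compatible_tracks(ip, input)
  regions <- vector("list", nrow(genes))
  if (region == "stop200") {
    stopw <- stop_codon_intervals(genes)
    stopw$start <- stopw$start - as.integer(stop_flank)
    stopw$end <- stopw$end + as.integer(stop_flank)
    if (!is.null(genome)) {
      clipped <- stopw$start < 0 | stopw$end > genome[stopw$chrom]
      if (any(clipped)) warning("region clipped to chromosome bounds for ",
                                sum(clipped), " gene(s)")
      stopw <- .clip_to_genome(stopw, genome)
    } else stopw$start <- pmax(stopw$start, 0L)
    regions <- lapply(genes$gene_id, function(g)
      stopw[stopw$gene_id == g, , drop = FALSE])
  } else {
    if (is.null(peaks)) stop("region = 'peaks' requires a peak table",
                             call. = FALSE)
    ex <- gene_exons(genes)
    plen <- peaks$end - peaks$start
    regions <- lapply(seq_len(nrow(genes)), function(i) {
      gid <- genes$gene_id[i]
      gr <- ex[ex$gene_id == gid, , drop = FALSE]
      if (nrow(peaks) == 0) return(peaks)
      ov <- .overlap_bp_with_set(peaks, gr)
      peaks[ov / plen > 0.5, , drop = FALSE]
    })
  }
  intensity <- vapply(regions, function(r) {
    if (is.null(r) || nrow(r) == 0) return(NA_real_)
    ipc <- sum(vapply(seq_len(nrow(r)), function(j)
      .region_count(ip, r$chrom[j], r$start[j], r$end[j]), numeric(1)))
    inc <- sum(vapply(seq_len(nrow(r)), function(j)
      .region_count(input, r$chrom[j], r$start[j], r$end[j]), numeric(1)))
    log2((ipc * 1e6 / ip$library_size + 1) /
         (inc * 1e6 / input$library_size + 1))
  }, numeric(1))
  data.frame(gene_id = genes$gene_id, intensity = intensity,
             region = region, stringsAsFactors = FALSE)
}

#' Metagene profile of IP and input signal
#'
#' Each feature's per-bp RPM signal is read 5'->3' (strand-flipped for minus
#' strand), length-scaled to \code{n_bins} positions by averaging, and
#' averaged across features. Genes use exon-projected coordinates (introns
#' excised); TE copies or plain intervals use their genomic span.
#'
#' @param ip,input \code{coverage_track}s.
#' @param features a gene-model data.frame (with \code{exon_starts}) or an
#'   interval data.frame (e.g. full-length MERVL copies).
#' @param n_bins number of scaled positions (default 100).
#' @return data.frame: bin, ip_mean, input_mean, n_features.
#' @export
metagene_profile <- function(ip, input, features, n_bins = 100) {
  .check_compatible_tracks(ip, input)
  if (nrow(features) == 0) stop("empty feature list", call. = FALSE)
  is_genes <- "exon_starts" %in% names(features)
  acc_ip <- acc_in <- numeric(n_bins)
  n_used <- 0L
  for (i in seq_len(nrow(features))) {
    if (is_genes) {
      es <- .unpack(features$exon_starts[i]); ee <- .unpack(features$exon_ends[i])
      ch <- features$chrom[i]; strand <- features$strand[i]
      sig_ip <- unlist(lapply(seq_along(es), function(j)
        .region_signal_bp(ip, ch, es[j], ee[j])))
      sig_in <- unlist(lapply(seq_along(es), function(j)
        .region_signal_bp(input, ch, es[j], ee[j])))
    } else {
      ch <- features$chrom[i]; strand <- features$strand[i]
      sig_ip <- .region_signal_bp(ip, ch, features$start[i], features$end[i])
      sig_in <- .region_signal_bp(input, ch, features$start[i], features$end[i])
    }
    L <- length(sig_ip)
    if (L < n_bins) next
    if (identical(strand, "-")) { sig_ip <- rev(sig_ip); sig_in <- rev(sig_in) }
    idx <- floor((seq_len(L) - 1) / L * n_bins) + 1L
    acc_ip <- acc_ip + tapply(sig_ip, idx, mean)
    acc_in <- acc_in + tapply(sig_in, idx, mean)
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop("no feature long enough for the requested bin count",
                        call. = FALSE)
  data.frame(bin = seq_len(n_bins), ip_mean = acc_ip / n_used,
             input_mean = acc_in / n_used, n_features = n_used,
             row.names = NULL)
}

#' Replicate concordance on high-CV genes
#'
#' Selects the \code{top_k} genes by coefficient of variation of the linear
#' fold enrichment (2^intensity) across samples, then computes all pairwise
#' Pearson correlations of intensity on that subset.
#'
#' @param intensity_mat numeric matrix, genes x samples, of log2 IP/input
#'   intensities.
#' @param top_k number of genes kept (default 2000; capped at available).
#' @return List with \code{correlation} (samples x samples matrix) and
#'   \code{genes_used}.
#' @export
replicate_concordance <- function(intensity_mat, top_k = 2000) {
  stopifnot(is.matrix(intensity_mat), ncol(intensity_mat) >= 2)
  fe <- 2^intensity_mat
  cv <- apply(fe, 1, function(v) stats::sd(v) / mean(v))
  cv[!is.finite(cv)] <- -Inf
  keep <- order(cv, decreasing = TRUE)[seq_len(min(top_k, nrow(fe)))]
  sub <- intensity_mat[keep, , drop = FALSE]
  ns <- ncol(sub)
  cm <- diag(1, ns)
  dimnames(cm) <- list(colnames(sub), colnames(sub))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    cm[i, j] <- cm[j, i] <- pearson_r(sub[, i], sub[, j])
  }
  list(correlation = cm, genes_used = rownames(sub))
}

#' Fraction of m6A-positive genes per expression decile
#'
#' Genes are binned into deciles of expression; per bin, the fraction of
#' m6A-positive genes is reported with an exact binomial confidence
#' interval.
#'
#' @param status data.frame from [gene_m6a_status()].
#' @param expression named numeric vector of expression values (by gene_id).
#' @param n_bins number of quantile bins (default 10).
#' @param conf confidence level (default 0.95).
#' @return data.frame: bin, n, frac_m6a, ci_lo, ci_hi, mean_expression.
#' @export
m6a_by_expression_bin <- function(status, expression, n_bins = 10,
                                  conf = 0.95) {
  e <- expression[status$gene_id]
  stopifnot(!any(is.na(e)))
  br <- stats::quantile(e, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(e, breaks = unique(br), include.lowest = TRUE, labels = FALSE)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    k <- sum(status$status[sel]); n <- sum(sel)
    ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
    data.frame(bin = b, n = n, frac_m6a = k / n, ci_lo = ci[1], ci_hi = ci[2],
               mean_expression = mean(e[sel]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn partition cardinalities of 2 or 3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return Named integer vector of exclusive Venn region sizes (names like
#'   \code{"A"}, \code{"A&B"}, ...), plus attribute \code{"union"} with the
#'   union cardinality.
#' @export
set_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2, 3),
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(sets))
  key <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&")))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "union") <- length(universe)
  counts
}
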