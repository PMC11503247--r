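#' Observed peak counts per feature set
#'
#' A peak counts toward a feature class iff more than 50% of the *peak's*
#' length is covered by the (reduced) union of that class's intervals.
#' Classes are counted independently, so one peak may count toward several.
#'
#' @param peaks interval data.frame.
#' @param feature_sets named list of interval data.frames (e.g. from
#'   [derive_features()] or [te_feature_sets()]).
#' @param min_fraction overlap fraction that must be exceeded (default 0.5;
#'   strictly greater-than).
#' @return Named integer vector of observed counts.
#' @export
observed_counts <- function(peaks, feature_sets, min_fraction = 0.5) {
  validate_intervals(peaks)
  .observed_counts_prepped(peaks, lapply(feature_sets, .prep_feature_set),
                           min_fraction)
}

## internal: per-chrom reduced IRanges representation of a feature set
.prep_feature_set <- function(f) {
  if (nrow(f) == 0) return(list())
  lapply(split(f, f$chrom), function(d) IRanges::reduce(.as_iranges(d)))
}

## internal: observed counts against pre-reduced feature sets
.observed_counts_prepped <- function(peaks, prepped, min_fraction = 0.5) {
  n <- nrow(peaks)
  if (n == 0)
    return(vapply(prepped, function(f) 0L, integer(1)))
  by_chrom <- split(seq_len(n), peaks$chrom)
  qr <- lapply(by_chrom, function(idx)
    .as_iranges(peaks[idx, , drop = FALSE]))
  plen <- peaks$end - peaks$start
  vapply(prepped, function(f) {
    ov <- numeric(n)
    for (ch in names(qr)) {
      sr <- f[[ch]]
      if (is.null(sr) || length(sr) == 0) next
      hits <- IRanges::findOverlaps(qr[[ch]], sr)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      w <- IRanges::width(IRanges::pintersect(qr[[ch]][qh],
                                              sr[S4Vectors::subjectHits(hits)]))
      idx <- by_chrom[[ch]]
      ov[idx] <- ov[idx] + as.numeric(
        tapply(w, factor(qh, levels = seq_along(qr[[ch]])), sum,
               default = 0))
    }
    sum(ov / plen > min_fraction)
  }, integer(1))
}

#' Shuffle-null enrichment table for peaks over feature sets
#'
#' The enrichment score of the peak-feature analysis: for each feature set,
#' the observed peak count O is compared with the expected count E-bar, the
#' mean count over \code{n_draws} length- and chromosome-preserving uniform
#' shuffles of the peak set. The score is
#' \code{E = log2((O + eps) / (Ebar + eps))} with pseudo-count
#' \code{eps = 0.5}; a score > 0 indicates enrichment. The empirical
#' enrichment p-value is \code{(1 + #draws with count >= O) / (1 + n_draws)}.
#'
#' @param peaks interval data.frame.
#' @param feature_sets named list of interval data.frames.
#' @param genome genome table.
#' @param seed integer seed for the shuffles.
#' @param n_draws number of shuffle draws averaged into the expectation
#'   (default 100; 1 gives single-draw tool mimicry).
#' @param eps pseudo-count in the log ratio (default 0.5).
#' @return data.frame: feature, observed, expected, score, empirical_p,
#'   n_draws, degenerate (TRUE for empty feature sets).
#' @export
enrichment_table <- function(peaks, feature_sets, genome, seed,
                             n_draws = 100, eps = 0.5) {
  stopifnot(n_draws >= 1)
  prepped <- lapply(feature_sets, .prep_feature_set)
  obs <- .observed_counts_prepped(peaks, prepped)
  draws <- shuffle_intervals(peaks, genome, seed = seed, n_draws = n_draws)
  nullcounts <- vapply(draws, .observed_counts_prepped,
                       integer(length(feature_sets)), prepped = prepped)
  nullcounts <- matrix(nullcounts, nrow = length(feature_sets))
  ebar <- rowMeans(nullcounts)
  ge <- rowSums(nullcounts >= matrix(obs, nrow = length(obs),
                                     ncol = n_draws))
  degenerate <- vapply(feature_sets, function(f) nrow(f) == 0, logical(1))
  score <- log2((obs + eps) / (ebar + eps))
  score[degenerate] <- 0
  data.frame(feature = names(feature_sets),
             observed = as.integer(obs),
             expected = ebar,
             score = score,
             empirical_p = (1 + ge) / (1 + n_draws),
             n_draws = n_draws,
             degenerate = degenerate,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#' @param x result of [enrichment_table()].
#' @param path file path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
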