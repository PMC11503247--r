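#' Log-normalise single-cell counts
#'
#' Per cell: \code{ln(1 + count / colsum * scale)} with \code{scale = 1e4}
#' by default. Cells with zero total counts are dropped with a warning.
#' Scale-invariant per cell (doubling a cell's counts leaves its normalised
#' vector unchanged).
#'
#' @param counts genes x cells matrix of non-negative counts.
#' @param scale size-factor target (default 1e4).
#' @return Normalised matrix (possibly with fewer columns).
#' @export
normalize_cells <- function(counts, scale = 1e4) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " cell(s) with zero total counts")
    counts <- counts[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  log1p(sweep(counts, 2, tot, "/") * scale)
}

#' Select highly variable genes
#'
#' Ranks genes by standardised variance: the per-gene variance of the
#' normalised values divided by a mean-variance trend estimated by a running
#' median over genes ordered by mean expression. Constant genes are
#' excluded; ties break deterministically by gene id.
#'
#' @param normalized matrix from [normalize_cells()].
#' @param n number of genes to return (default 500; capped at available).
#' @param window running-median window (odd; default 21).
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvg <- function(normalized, n = 500, window = 21) {
  mu <- rowMeans(normalized)
  v <- apply(normalized, 1, stats::var)
  keep <- v > 0
  mu <- mu[keep]; v <- v[keep]
  ids <- rownames(normalized)[keep]
  o <- order(mu)
  w <- min(window, if (length(v) %% 2 == 0) length(v) - 1 else length(v))
  if (w < 1) w <- 1
  trend <- numeric(length(v))
  trend[o] <- stats::runmed(v[o], k = w)
  sv <- v / pmax(trend, .Machine$double.eps)
  ids[order(-sv, ids)][seq_len(min(n, length(ids)))]
}

#' Assign cells to 2CLC / transient / pluripotent states by marker scores
#'
#' Per cell, each marker set's score is the mean normalised expression over
#' its genes. A cell is 2CLC when its 2CLC score is above threshold and its
#' pluripotency score below; pluripotent in the reverse case; transient
#' otherwise (both high, or both intermediate/low). Thresholds default to
#' the midpoint of a 2-component Gaussian fit of each score distribution
#' (falling back to the 60th percentile when the fit is degenerate).
#'
#' @param normalized matrix from [normalize_cells()].
#' @param markers_2clc,markers_plurip disjoint non-empty marker gene sets.
#' @param thresholds optional numeric length-2 vector
#'   \code{c(thr_2clc, thr_plurip)} overriding the fitted thresholds.
#' @return data.frame: cell, score_2clc, score_plurip, state.
#' @export
assign_states <- function(normalized, markers_2clc, markers_plurip,
                          thresholds = NULL) {
  stopifnot(length(markers_2clc) > 0, length(markers_plurip) > 0,
            length(intersect(markers_2clc, markers_plurip)) == 0)
  score_of <- function(markers, label) {
    present <- intersect(markers, rownames(normalized))
    if (length(present) == 0)
      stop("unusable markers: no ", label, " marker present in the matrix",
           call. = FALSE)
    if (length(present) < length(markers))
      warning(length(markers) - length(present), " ", label,
              " marker(s) absent from the matrix; dropped")
    colMeans(normalized[present, , drop = FALSE])
  }
  s2 <- score_of(markers_2clc, "2CLC")
  sp <- score_of(markers_plurip, "pluripotent")
  if (is.null(thresholds))
    thresholds <- c(.bimodal_threshold(s2), .bimodal_threshold(sp))
  lab <- ifelse(s2 >= thresholds[1] & sp < thresholds[2], "2CLC",
         ifelse(sp >= thresholds[2] & s2 < thresholds[1], "pluripotent",
                "transient"))
  data.frame(cell = colnames(normalized), score_2clc = unname(s2),
             score_plurip = unname(sp), state = unname(lab),
             row.names = NULL, stringsAsFactors = FALSE)
}

## internal: threshold between the two modes of a score distribution.
## Equal-variance 2-component Gaussian mixture fitted by EM (initialised
## from the outer quartiles); threshold = midpoint of the component means.
## Falls back to the 60th percentile when the fit is degenerate (components
## closer than a tenth of the score range, or no spread at all).
.bimodal_threshold <- function(scores, max_iter = 200, tol = 1e-8) {
  rng <- diff(range(scores))
  fallback <- unname(stats::quantile(scores, 0.6))
  if (rng == 0 || length(scores) < 4) return(fallback)
  mu <- unname(stats::quantile(scores, c(0.25, 0.75)))
  s2 <- stats::var(scores) / 4
  pi1 <- 0.5
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(scores, mu[1], sqrt(s2))
    d2 <- (1 - pi1) * stats::dnorm(scores, mu[2], sqrt(s2))
    g <- d1 / pmax(d1 + d2, .Machine$double.xmin)
    mu_new <- c(sum(g * scores) / sum(g),
                sum((1 - g) * scores) / sum(1 - g))
    s2_new <- sum(g * (scores - mu_new[1])^2 +
                    (1 - g) * (scores - mu_new[2])^2) / length(scores)
    s2_new <- max(s2_new, 1e-12)
    pi_new <- mean(g)
    done <- max(abs(mu_new - mu)) < tol
    mu <- mu_new; s2 <- s2_new; pi1 <- min(max(pi_new, 1e-6), 1 - 1e-6)
    if (done) break
  }
  if (abs(diff(mu)) < 0.1 * rng) return(fallback)
  mean(mu)
}

#' Per-state mean expression matrix
#'
#' Mean normalised expression per gene within each state; optionally
#' restricted to given gene sets and/or row-scaled (z-score across states,
#' presentation only). Invariant under cell permutation.
#'
#' @param normalized matrix from [normalize_cells()].
#' @param labels data.frame from [assign_states()] (or any cell/state table).
#' @param genes optional character vector restricting rows.
#' @param row_scale z-score rows across states (default FALSE).
#' @return genes x states numeric matrix.
#' @export
cluster_mean_matrix <- function(normalized, labels, genes = NULL,
                                row_scale = FALSE) {
  st <- stats::setNames(labels$state, labels$cell)[colnames(normalized)]
  stopifnot(!any(is.na(st)))
  if (!is.null(genes))
    normalized <- normalized[intersect(genes, rownames(normalized)), ,
                             drop = FALSE]
  states <- unique(st)
  m <- vapply(states, function(s)
    rowMeans(normalized[, st == s, drop = FALSE]), numeric(nrow(normalized)))
  m <- matrix(m, nrow = nrow(normalized),
              dimnames = list(rownames(normalized), states))
  if (row_scale) m <- t(scale(t(m)))
  m
}

#' Fold-change contrast between gene sets along the state transition
#'
#' Per gene, FC = (mean in the destination state + eps) / (mean in the
#' origin state + eps), eps = 0.01 by default. The log2 FCs of gene set A
#' are contrasted against those of set B with the two-tailed Wilcoxon
#' rank-sum test — the readout for "m6A+ ZGA transcripts decline faster
#' than m6A- ones" along the 2CLC -> pluripotent transition.
#'
#' @param means genes x states matrix from [cluster_mean_matrix()].
#' @param set_a,set_b character gene sets.
#' @param from,to origin and destination states (defaults 2CLC,
#'   pluripotent).
#' @param eps pseudo-mean (default 0.01).
#' @return List with \code{fc} (data.frame gene_id, set, log2fc),
#'   \code{median_a}, \code{median_b}, \code{p_value}.
#' @export
state_fold_change <- function(means, set_a, set_b, from = "2CLC",
                              to = "pluripotent", eps = 0.01) {
  if (!all(c(from, to) %in% colnames(means)))
    stop("missing state: ", from, " and ", to,
         " must both be present in the mean matrix", call. = FALSE)
  fc_of <- function(set) {
    g <- intersect(set, rownames(means))
    log2((means[g, to] + eps) / (means[g, from] + eps))
  }
  fa <- fc_of(set_a); fb <- fc_of(set_b)
  w <- wilcoxon_rank_sum(fa, fb)
  list(fc = data.frame(gene_id = c(names(fa), names(fb)),
                       set = rep(c("A", "B"), c(length(fa), length(fb))),
                       log2fc = c(unname(fa), unname(fb)),
                       stringsAsFactors = FALSE),
       median_a = stats::median(fa), median_b = stats::median(fb),
       p_value = w$p_value)
}
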