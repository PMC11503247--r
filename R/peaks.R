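#' Call m6A peaks from IP vs input binned coverage
#'
#' Sliding-window count test: for every window of \code{window_bins}
#' consecutive bins (step one bin), the IP count is tested against a null
#' whose mean is the input count in that window scaled by the ratio of
#' library sizes, floored at a pseudo-mean of 1 read. The null law is
#' Poisson when \code{dispersion = 0}; by default an excess-dispersion
#' coefficient is estimated robustly from the genome-wide Poisson residuals
#' (median-absolute-deviation within mean-deciles, regression of excess
#' variance on the mean) and the test uses a negative binomial with that
#' dispersion, which keeps the false-call rate at its nominal level on
#' overdispersed coverage while reducing to the pure Poisson test on
#' Poisson data. P-values are BH-adjusted across all tested windows;
#' significant windows (q < \code{alpha_q}) that overlap or lie within
#' \code{merge_gap_bins} bins of each other are merged into peaks. Per
#' peak, the summit is the maximum-IP bin and the fold enrichment is
#' \code{(IP RPM + 1) / (input RPM + 1)} over the merged span.
#' Deterministic; invariant under equal scaling of both library sizes.
#'
#' @param ip,input \code{coverage_track}s with matching bin size and genome.
#' @param window_bins window width in bins (default 2, i.e. 100 bp at 50-bp
#'   bins).
#' @param merge_gap_bins maximum gap (in bins) between significant windows
#'   merged into one peak (default 1).
#' @param alpha_q BH q-value threshold (default 0.05).
#' @param dispersion \code{"auto"} (default) to estimate the excess
#'   dispersion from the data, or a non-negative number (0 = exact Poisson
#'   test).
#' @return Peak data.frame: chrom, start, end, strand, summit_offset,
#'   fold_enrichment, p_value, q_value; attribute \code{"dispersion"} holds
#'   the dispersion used.
#' @export
call_peaks <- function(ip, input, window_bins = 2, merge_gap_bins = 1,
                       alpha_q = 0.05, dispersion = "auto") {
  .check_compatible_tracks(ip, input)
  stopifnot(window_bins >= 1)
  bs <- ip$bin_size
  scale <- ip$library_size / input$library_size
  win <- list()
  for (ch in names(ip$counts)) {
    vi <- ip$counts[[ch]]; vb <- input$counts[[ch]]
    nb <- length(vi)
    if (nb < window_bins) next
    k <- nb - window_bins + 1L
    csum <- function(v) {
      cs <- c(0, cumsum(v))
      cs[(window_bins + 1):(nb + 1)] - cs[1:k]
    }
    ipw <- csum(vi); inw <- csum(vb)
    lambda <- pmax(inw * scale, 1)
    win[[ch]] <- data.frame(chrom = ch, bin0 = seq_len(k) - 1L,
                            ipw = ipw, inw = inw, lambda = lambda,
                            stringsAsFactors = FALSE)
  }
  if (length(win) == 0) return(.empty_peaks())
  wdf <- do.call(rbind, win)
  d <- if (identical(dispersion, "auto"))
    .estimate_excess_dispersion(wdf$ipw, wdf$lambda) else as.numeric(dispersion)
  stopifnot(d >= 0)
  p_rate <- if (d < 1e-10)
    stats::ppois(wdf$ipw - 1, wdf$lambda, lower.tail = FALSE)
  else
    stats::pnbinom(wdf$ipw - 1, mu = wdf$lambda, size = 1 / d,
                   lower.tail = FALSE)
  ## exact conditional Poisson-ratio test: IP out of IP + input, which
  ## absorbs the sampling noise of the input track that the scaled-mean
  ## test cannot see at low coverage
  p0 <- ip$library_size / (ip$library_size + input$library_size)
  p_cond <- stats::pbinom(wdf$ipw - 1, wdf$ipw + wdf$inw, p0,
                          lower.tail = FALSE)
  wdf$p <- pmax(p_rate, p_cond)
  wdf$q <- bh_fdr(wdf$p)
  sig <- wdf[wdf$q < alpha_q, , drop = FALSE]
  if (nrow(sig) == 0) return(structure(.empty_peaks(), dispersion = d))
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$bin0), , drop = FALSE]
    ## window i covers bins [bin0, bin0 + window_bins); merge if gap <= merge_gap_bins
    grp <- cumsum(c(1, diff(s$bin0) > window_bins + merge_gap_bins))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      b0 <- min(sg$bin0); b1 <- max(sg$bin0) + window_bins
      start <- b0 * bs
      end <- min(b1 * bs, length(ip$counts[[ch]]) * bs)
      vbin <- ip$counts[[ch]][(b0 + 1):b1]
      summit_bin <- which.max(vbin) - 1L
      ip_rpm <- sum(ip$counts[[ch]][(b0 + 1):b1]) * 1e6 / ip$library_size
      in_rpm <- sum(input$counts[[ch]][(b0 + 1):b1]) * 1e6 / input$library_size
      pmin_ <- min(sg$p)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = as.integer(start), end = as.integer(end),
        strand = ".", summit_offset = as.integer(summit_bin * bs),
        fold_enrichment = (ip_rpm + 1) / (in_rpm + 1),
        p_value = pmin_, q_value = min(sg$q),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dispersion") <- d
  res
}

## internal: robust estimate of the excess-dispersion coefficient d such
## that Var(IP | lambda) ~ lambda + d * lambda^2 across windows. Poisson
## residuals are pooled into deciles of lambda; each decile's variance is
## estimated by the squared scaled MAD (insensitive to the minority of true
## peak windows), and the excess over 1 is regressed on the decile mean of
## lambda through the origin. Clipped at 0.
.estimate_excess_dispersion <- function(ipw, lambda, min_lambda = 5) {
  sel <- lambda >= min_lambda
  if (sum(sel) < 50) return(0)
  r <- (ipw[sel] - lambda[sel]) / sqrt(lambda[sel])
  lam <- lambda[sel]
  dec <- cut(rank(lam, ties.method = "first"), breaks = 10, labels = FALSE)
  v <- tapply(r, dec, function(x) (stats::mad(x))^2)
  lm_ <- tapply(lam, dec, mean)
  excess <- pmax(v - 1, 0)
  max(0, sum(excess * lm_) / sum(lm_^2))
}

.empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), summit_offset = integer(0),
             fold_enrichment = numeric(0), p_value = numeric(0),
             q_value = numeric(0), stringsAsFactors = FALSE)
}

#' Precision and recall of called peaks against ground truth
#'
#' A called peak is a true positive when it overlaps any true peak by at
#' least one base; a true peak is recovered when any called peak overlaps
#' it. Precision = TP calls / calls, recall = recovered / truth.
#'
#' @param called,truth interval data.frames.
#' @return List with \code{precision}, \code{recall}, \code{n_called},
#'   \code{n_true}.
#' @export
peak_benchmark <- function(called, truth) {
  prec <- if (nrow(called) == 0) NA_real_ else
    mean(.overlap_bp_with_set(called, truth) > 0)
  rec <- if (nrow(truth) == 0) NA_real_ else
    mean(.overlap_bp_with_set(truth, called) > 0)
  list(precision = prec, recall = rec,
       n_called = nrow(called), n_true = nrow(truth))
}

#' Spike-in enrichment QC (GLuc/CLuc ratio)
#'
#' Antibody enrichment efficiency from methylated (GLuc) and unmethylated
#' (CLuc) spike-in RNAs: \code{R = (GLuc_IP/GLuc_input) / (CLuc_IP/CLuc_input)}.
#' With Ct inputs each IP/input ratio is computed as \code{2^-(Ct_IP -
#' Ct_input)}. A library passes QC when R meets the threshold.
#'
#' @param gluc_ip,gluc_input,cluc_ip,cluc_input positive counts, or Ct values
#'   when \code{ct = TRUE}.
#' @param threshold minimum passing ratio (default 5).
#' @param ct logical; interpret inputs as qPCR Ct values.
#' @return List with \code{ratio} and \code{pass}.
#' @examples
#' spike_in_qc(100, 10, 10, 10)$ratio  # 10
#' @export
spike_in_qc <- function(gluc_ip, gluc_input, cluc_ip, cluc_input,
                        threshold = 5, ct = FALSE) {
  vals <- c(gluc_ip, gluc_input, cluc_ip, cluc_input)
  if (!ct && any(vals <= 0))
    stop("invalid measurement: counts must be positive", call. = FALSE)
  if (any(!is.finite(vals)))
    stop("invalid measurement: non-finite value", call. = FALSE)
  if (ct) {
    g <- 2^(-(gluc_ip - gluc_input))
    c2 <- 2^(-(cluc_ip - cluc_input))
  } else {
    g <- gluc_ip / gluc_input
    c2 <- cluc_ip / cluc_input
  }
  r <- g / c2
  list(ratio = r, pass = r >= threshold)
}

#' RRACH motif density in peaks vs shuffled peaks
#'
#' Counts (possibly overlapping) occurrences of the m6A consensus 5-mer
#' RRACH (R = A/G, H = A/C/T on the DNA sense strand) within each interval's
#' sequence, on the annotated strand (unstranded intervals are read on the
#' plus strand). Densities are occurrences per kb; the ratio
#' peak-density / shuffled-density summarises motif enrichment.
#'
#' @param peaks,shuffled_peaks interval data.frames.
#' @param sequences \code{Biostrings::DNAStringSet} named by chromosome.
#' @return List with \code{peak_density}, \code{shuffled_density},
#'   \code{ratio} (per-kb densities).
#' @export
motif_density <- function(peaks, shuffled_peaks, sequences) {
  count_set <- function(df) {
    if (nrow(df) == 0) return(c(n = 0, bp = 0))
    if (!all(df$chrom %in% names(sequences)))
      stop("missing sequence for interval chromosome", call. = FALSE)
    n <- 0
    for (i in seq_len(nrow(df))) {
      s <- Biostrings::subseq(sequences[[df$chrom[i]]],
                              start = df$start[i] + 1L, end = df$end[i])
      if (identical(df$strand[i], "-")) s <- Biostrings::reverseComplement(s)
      n <- n + Biostrings::countPattern("RRACH", s, fixed = FALSE)
    }
    c(n = n, bp = sum(df$end - df$start))
  }
  p <- count_set(peaks); s <- count_set(shuffled_peaks)
  pd <- if (p["bp"] > 0) p["n"] / p["bp"] * 1000 else 0
  sd_ <- if (s["bp"] > 0) s["n"] / s["bp"] * 1000 else 0
  list(peak_density = unname(pd), shuffled_density = unname(sd_),
       ratio = unname(if (sd_ > 0) pd / sd_ else NA_real_))
}
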