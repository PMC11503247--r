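#' Genomic interval tables
#'
#' All coordinates in this package are 0-based, half-open: an interval
#' \code{[start, end)} covers bases \code{start, ..., end - 1}. This is the
#' native BED convention; GTF-like input is converted on read. A set of
#' intervals is an ordinary \code{data.frame} with columns \code{chrom}
#' (character), \code{start}, \code{end} (integer) and \code{strand}
#' (one of \code{"+"}, \code{"-"}, \code{"."}).
#'
#' @param chrom character vector of chromosome ids.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand characters, recycled; default \code{"."}.
#' @param ... additional metadata columns, recycled to length.
#' @return A validated interval \code{data.frame}.
#' @examples
#' genomic_intervals("chr1", 100, 200)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  chrom <- as.character(chrom)
  df <- data.frame(chrom = chrom,
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep(as.character(strand),
                                length.out = length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the structural invariants: \code{0 <= start < end}, strand in
#' \code{+,-,.}, and (when a genome table is supplied) \code{end} within the
#' chromosome length.
#'
#' @param x interval data.frame.
#' @param genome optional genome table (see [genome_table()]).
#' @return \code{x}, invisibly. Errors on violation.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end))
    stop("invalid interval: require 0 <= start < end", call. = FALSE)
  if (!is.null(x$strand) && !all(x$strand %in% c("+", "-", ".")))
    stop("invalid strand; must be one of '+', '-', '.'", call. = FALSE)
  if (!is.null(genome)) {
    if (!all(x$chrom %in% names(genome)))
      stop("interval on chromosome absent from genome table", call. = FALSE)
    if (any(x$end > genome[x$chrom]))
      stop("interval extends beyond chromosome end", call. = FALSE)
  }
  invisible(x)
}

#' Genome table
#'
#' A genome table maps chromosome ids to lengths in bp; it bounds interval
#' validation and shuffling.
#'
#' @param chrom character chromosome ids (unique).
#' @param length positive integer lengths in bp.
#' @return Named numeric vector of lengths.
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicate chromosome ids", call. = FALSE)
  if (any(length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  stats::setNames(length, chrom)
}

## internal: 0-based half-open df -> IRanges (1-based closed) for one chrom set
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.from_iranges <- function(ir, chrom, strand = ".") {
  if (length(ir) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  data.frame(chrom = chrom,
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             strand = strand,
             stringsAsFactors = FALSE)
}

## internal: per-chrom merge of overlapping/adjacent intervals
.reduce_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end", "strand")])
  out <- lapply(split(df, df$chrom), function(d) {
    .from_iranges(IRanges::reduce(.as_iranges(d)), chrom = d$chrom[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## internal: genome complement of a (possibly empty) interval set
.complement_intervals <- function(df, genome) {
  out <- lapply(names(genome), function(ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    ir <- IRanges::reduce(.as_iranges(d))
    gaps <- IRanges::gaps(ir, start = 1L, end = as.integer(genome[[ch]]))
    .from_iranges(gaps, chrom = ch)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of one interval covered by another
#'
#' Returns |a intersect b| / |a| — the proportion of the *first* interval's
#' length covered by the second. This is the quantity thresholded by the
#' ">50% of the peak" overlap rule used throughout the enrichment counting.
#' Vectorised elementwise over equal-length inputs.
#'
#' @param a,b interval data.frames of equal row count (or one of them single-row).
#' @return Numeric vector in \code{[0, 1]}; 0 when chromosomes differ.
#' @examples
#' a <- genomic_intervals("chr1", 100, 200)
#' b <- genomic_intervals("chr1", 150, 300)
#' overlap_fraction(a, b)  # 0.5 -- not counted under the > 50% rule
#' @export
overlap_fraction <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  idx_a <- if (nrow(a) == 1) rep(1L, n) else seq_len(n)
  idx_b <- if (nrow(b) == 1) rep(1L, n) else seq_len(n)
  ov <- pmax(0, pmin(a$end[idx_a], b$end[idx_b]) -
                pmax(a$start[idx_a], b$start[idx_b]))
  ov <- ifelse(a$chrom[idx_a] == b$chrom[idx_b], ov, 0)
  ov / (a$end[idx_a] - a$start[idx_a])
}

## internal: per-interval overlap (in bp) with the reduced union of a feature set
.overlap_bp_with_set <- function(x, feats) {
  if (nrow(x) == 0) return(numeric(0))
  res <- numeric(nrow(x))
  if (nrow(feats) == 0) return(res)
  feats <- .reduce_intervals(feats)
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    fd <- feats[feats$chrom == ch, , drop = FALSE]
    if (nrow(fd) == 0) next
    qr <- .as_iranges(x[xi, , drop = FALSE])
    sr <- .as_iranges(fd)
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(qr[qh], sr[sh]))
    res[xi] <- res[xi] + as.numeric(tapply(w, factor(qh, levels = seq_along(qr)),
                                           sum, default = 0))
  }
  res
}

#' Shuffle intervals over a genome
#'
#' Generates randomised placements of a peak set: each draw preserves every
#' peak's chromosome, length and strand, and places its start uniformly over
#' the valid positions \code{0 .. L - len}. Shuffled peaks may overlap each
#' other; nothing is excluded. This is the permutation null behind the
#' observed/expected enrichment score.
#'
#' @param peaks interval data.frame.
#' @param genome genome table.
#' @param seed integer seed; the draws are fully reproducible from it.
#' @param n_draws number of independent randomised sets (>= 1).
#' @return List of \code{n_draws} interval data.frames.
#' @export
shuffle_intervals <- function(peaks, genome, seed, n_draws = 100) {
  validate_intervals(peaks, genome)
  stopifnot(n_draws >= 1)
  len <- peaks$end - peaks$start
  maxstart <- genome[peaks$chrom] - len
  if (any(maxstart < 0))
    stop("peak longer than its chromosome: no valid placement", call. = FALSE)
  ## random starts are assigned in a canonical peak order so that the draw
  ## sets (and everything downstream) are invariant to input permutation
  ord <- order(peaks$chrom, len, peaks$start, peaks$strand)
  inv <- order(ord)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_draws), function(i) {
      ns <- floor(stats::runif(nrow(peaks)) * (maxstart[ord] + 1))[inv]
      data.frame(chrom = peaks$chrom,
                 start = as.integer(ns),
                 end = as.integer(ns + len),
                 strand = peaks$strand,
                 stringsAsFactors = FALSE)
    })
  })
}
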