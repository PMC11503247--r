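#' Binned coverage tracks
#'
#' A coverage track holds per-chromosome vectors of non-negative read counts
#' in fixed-width bins, together with the library size used for
#' reads-per-million (RPM) normalisation, a label (\code{"IP"} or
#' \code{"input"}) and a condition tag. The final bin of a chromosome may be
#' shorter than \code{bin_size}.
#'
#' @param counts named list (by chrom) of non-negative integer vectors.
#' @param bin_size bin width in bp.
#' @param label \code{"IP"} or \code{"input"}.
#' @param condition condition string (e.g. \code{"2CLC"}, \code{"ESC"}).
#' @param library_size total read count; defaults to the sum of bins.
#' @return Object of class \code{coverage_track}.
#' @export
coverage_track <- function(counts, bin_size, label = c("IP", "input"),
                           condition = "NA", library_size = NULL) {
  label <- match.arg(label)
  stopifnot(is.list(counts), !is.null(names(counts)), bin_size >= 1)
  counts <- lapply(counts, function(v) {
    if (any(v < 0)) stop("negative bin count", call. = FALSE)
    as.numeric(v)
  })
  total <- sum(vapply(counts, sum, numeric(1)))
  if (is.null(library_size)) library_size <- total
  if (total > library_size + 1e-8)
    stop("sum of bins exceeds library_size", call. = FALSE)
  structure(list(counts = counts, bin_size = as.integer(bin_size),
                 label = label, condition = condition,
                 library_size = library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s / %s, bin %d bp, %d chroms, library %.0f\n",
              x$label, x$condition, x$bin_size, length(x$counts),
              x$library_size))
  invisible(x)
}

.check_compatible_tracks <- function(a, b) {
  if (a$bin_size != b$bin_size)
    stop("incompatible tracks: bin sizes differ", call. = FALSE)
  if (!identical(sort(names(a$counts)), sort(names(b$counts))))
    stop("incompatible tracks: chromosome sets differ", call. = FALSE)
  if (a$library_size <= 0 || b$library_size <= 0)
    stop("degenerate input: zero library size", call. = FALSE)
  invisible(TRUE)
}

## internal: counts of track `x` summed over one 0-based half-open interval,
## with partial bins weighted by their overlapped fraction
.region_count <- function(x, chrom, start, end) {
  v <- x$counts[[chrom]]
  if (is.null(v)) return(0)
  bs <- x$bin_size
  start <- max(start, 0); end <- min(end, length(v) * bs)
  if (start >= end) return(0)
  b0 <- floor(start / bs); b1 <- ceiling(end / bs) - 1
  idx <- (b0:b1) + 1L
  binstart <- (b0:b1) * bs
  w <- (pmin(binstart + bs, end) - pmax(binstart, start)) / bs
  sum(v[idx] * w)
}

## internal: per-bp RPM-normalised signal over an interval (vector length end-start)
.region_signal_bp <- function(x, chrom, start, end) {
  v <- x$counts[[chrom]]
  bs <- x$bin_size
  pos <- start:(end - 1)
  idx <- floor(pos / bs) + 1L
  idx[idx < 1 | idx > length(v)] <- NA
  sig <- ifelse(is.na(idx), 0, v[pmax(idx, 1)] / bs)
  sig * 1e6 / x$library_size
}

#' Read / write coverage as bedGraph-style TSV
#'
#' Four columns (chrom, start, end, count), one row per bin including zero
#' bins, written through rtracklayer's bedGraph support.
#'
#' @param path file path.
#' @param genome genome table (defines bin counts per chromosome on read).
#' @param bin_size bin width in bp.
#' @param label,condition,library_size track metadata (not stored in the
#'   bedGraph itself).
#' @return A \code{coverage_track}.
#' @export
read_coverage <- function(path, genome, bin_size, label = "IP",
                          condition = "NA", library_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  counts <- lapply(stats::setNames(names(genome), names(genome)), function(ch) {
    numeric(ceiling(genome[[ch]] / bin_size))
  })
  ch <- as.character(GenomicRanges::seqnames(gr))
  bin <- (GenomicRanges::start(gr) - 1L) %/% bin_size + 1L
  sc <- gr$score
  for (c2 in unique(ch)) {
    sel <- ch == c2
    counts[[c2]][bin[sel]] <- sc[sel]
  }
  coverage_track(counts, bin_size, label = label, condition = condition,
                 library_size = library_size)
}

#' @rdname read_coverage
#' @param x a \code{coverage_track}.
#' @export
write_coverage <- function(x, path) {
  nb <- vapply(x$counts, length, integer(1))
  st <- unlist(lapply(nb, function(n) (seq_len(n) - 1L) * x$bin_size),
               use.names = FALSE)
  gr <- GenomicRanges::GRanges(rep(names(x$counts), nb),
                               IRanges::IRanges(st + 1L, st + x$bin_size),
                               score = unlist(x$counts, use.names = FALSE))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
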