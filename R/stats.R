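#' Two-tailed unpaired Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. For
#' \code{length(x) + length(y) <= exact_max} and no ties the null
#' distribution of the U statistic is enumerated exactly over all
#' \code{choose(n, nx)} group labelings; otherwise a normal approximation
#' with tie correction and continuity correction is used. Two-tailed p-value
#' is \code{min(1, 2 * min(P(U <= u), P(U >= u)))} in exact mode.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest combined sample size for exact enumeration
#'   (default 12).
#' @return List with \code{statistic} (U for the first sample),
#'   \code{p_value}, \code{method} ("exact" or "normal-approx").
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  if (length(x) < 1 || length(y) < 1)
    stop("insufficient data: both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (n <= exact_max && !ties) {
    ## exact: enumerate rank subsets of size nx; U = sum(ranks) - nx(nx+1)/2
    combs <- utils::combn(n, nx)
    us <- colSums(matrix(seq_len(n)[combs], nrow = nx)) - nx * (nx + 1) / 2
    p_le <- mean(us <= u + 1e-9)
    p_ge <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tab <- table(pooled)
    tiecor <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tiecor)
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                                 method = "normal-approx"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  list(statistic = u, p_value = max(p, .Machine$double.xmin), method = method)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-tailed p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of tables whose probability does
#' not exceed that of the observed table (with a small relative tolerance
#' for floating-point ties). The sample odds ratio \code{ad/bc} is reported,
#' with a Haldane correction of +0.5 per cell when any cell is zero.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return List with \code{p_value}, \code{odds_ratio}, \code{method}.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))$p_value  # 1/3
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(tab < 0)) stop("invalid table: negative cell", call. = FALSE)
  if (sum(tab) == 0) stop("invalid table: empty table", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b                     # row-1 total
  k <- a + c2                    # col-1 total
  n <- sum(tab)
  lo <- max(0, k - (n - m)); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  orr <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c2 + 0.5))
         else (a * d) / (b * c2)
  list(p_value = min(1, p), odds_ratio = orr, method = "exact")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: \code{q_(i) = min_{j >= i} p_(j) * m / j},
#' capped at 1 and returned in the input order. Never smaller than the
#' corresponding p-value.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return Numeric vector of q-values aligned to \code{p}.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  pmax(out, p)     # guard 1-ulp float dips below the input p-value
}

#' Welch's t-test on log2(value + 1)
#'
#' Two-tailed Welch (unequal-variance) t-test applied to
#' \code{log2(v + 1)}-transformed values, with Satterthwaite degrees of
#' freedom. Used as the replicate-level test behind DEG calling.
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
welch_t_log <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient data: need >= 2 values per group", call. = FALSE)
  lx <- log2(x + 1); ly <- log2(y + 1)
  vx <- stats::var(lx) / length(lx); vy <- stats::var(ly) / length(ly)
  if (vx + vy == 0) {
    eq <- isTRUE(all.equal(mean(lx), mean(ly)))
    return(list(statistic = if (eq) 0 else Inf, df = NA_real_,
                p_value = if (eq) 1 else .Machine$double.xmin))
  }
  t <- (mean(lx) - mean(ly)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(lx) - 1) + vy^2 / (length(ly) - 1))
  list(statistic = t, df = df,
       p_value = max(2 * stats::pt(-abs(t), df), .Machine$double.xmin))
}

#' Pearson correlation coefficient
#'
#' Direct moment formula; requires non-degenerate variance in both inputs.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Correlation in \code{[-1, 1]}.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) stop("zero variance: correlation undefined", call. = FALSE)
  max(-1, min(1, sum(dx * dy) / den))
}
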