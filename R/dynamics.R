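#' Call differentially expressed genes at the printed cut-offs
#'
#' Expression values are normalised to counts-per-million per replicate
#' (default), fold change is computed from replicate means with a small
#' pseudo-count, the p-value per gene from Welch's t on log2(CPM + 1), and
#' q-values by Benjamini-Hochberg. A gene is \code{up} iff FC > \code{fc_cut}
#' and q < \code{q_cut} (strict inequalities, matching the printed
#' "FC > 2 and FDR < 0.05"), \code{down} symmetrically, else \code{ns}.
#'
#' @param expr numeric matrix, genes x samples, raw counts or abundances.
#' @param conditions character vector, one condition per column.
#' @param cond_a,cond_b the two contrasted conditions (FC = A/B).
#' @param fc_cut,q_cut cut-offs (defaults 2 and 0.05).
#' @param normalize \code{"cpm"} or \code{"none"}.
#' @param pseudo pseudo-count added to replicate means before the ratio
#'   (default 0.5).
#' @return data.frame: gene_id, mean_a, mean_b, log2fc, p_value, q_value,
#'   direction.
#' @export
call_degs <- function(expr, conditions, cond_a = "2CLC", cond_b = "ESC",
                      fc_cut = 2, q_cut = 0.05,
                      normalize = c("cpm", "none"), pseudo = 0.5) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(expr), length(conditions) == ncol(expr))
  ia <- which(conditions == cond_a); ib <- which(conditions == cond_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("insufficient replication: need >= 2 replicates per condition",
         call. = FALSE)
  m <- expr
  if (normalize == "cpm") m <- sweep(m, 2, colSums(m), "/") * 1e6
  ma <- rowMeans(m[, ia, drop = FALSE]); mb <- rowMeans(m[, ib, drop = FALSE])
  log2fc <- log2((ma + pseudo) / (mb + pseudo))
  p <- vapply(seq_len(nrow(m)), function(i)
    welch_t_log(m[i, ia], m[i, ib])$p_value, numeric(1))
  q <- bh_fdr(p)
  fc <- 2^abs(log2fc)
  direction <- rep("ns", nrow(m))
  direction[fc > fc_cut & q < q_cut & log2fc > 0] <- "up"
  direction[fc > fc_cut & q < q_cut & log2fc < 0] <- "down"
  data.frame(gene_id = rownames(expr), mean_a = ma, mean_b = mb,
             log2fc = log2fc, p_value = p, q_value = q,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify m6A dynamics between two conditions
#'
#' Pure mapping of the per-gene (condition-A status, condition-B status)
#' pair, with A = 2CLC and B = ESC by default:
#' (+,-) -> gain (2CLC-specific methylation), (+,+) -> keep,
#' (-,+) -> lose (ESC-specific), (-,-) -> none.
#'
#' @param status data.frame with gene_id, condition, status rows for both
#'   conditions (see [gene_m6a_status()]).
#' @param cond_a,cond_b the two conditions (default 2CLC vs ESC).
#' @return data.frame: gene_id, class (gain/keep/lose/none).
#' @export
classify_m6a_dynamics <- function(status, cond_a = "2CLC", cond_b = "ESC") {
  sa <- status[status$condition == cond_a, c("gene_id", "status")]
  sb <- status[status$condition == cond_b, c("gene_id", "status")]
  genes <- union(sa$gene_id, sb$gene_id)
  a <- stats::setNames(sa$status, sa$gene_id)[genes]
  b <- stats::setNames(sb$status, sb$gene_id)[genes]
  if (any(is.na(a)) || any(is.na(b)))
    stop("missing condition: every gene needs a status in both conditions",
         call. = FALSE)
  cls <- ifelse(a & !b, "gain",
         ifelse(a & b, "keep",
         ifelse(!a & b, "lose", "none")))
  data.frame(gene_id = genes, class = unname(cls), stringsAsFactors = FALSE)
}

#' Expression fold change by m6A dynamics class
#'
#' Groups genes' log2 fold changes by dynamics class and tests every class
#' pair with the two-tailed Wilcoxon rank-sum test. Empty classes are
#' omitted with a warning.
#'
#' @param degs DEG table from [call_degs()].
#' @param classes classification from [classify_m6a_dynamics()].
#' @param up_only restrict to up-regulated genes (default FALSE: all genes).
#' @return List with \code{summary} (class, n, median_log2fc, mean_log2fc)
#'   and \code{tests} (class_a, class_b, p_value).
#' @export
fc_by_dynamics_class <- function(degs, classes, up_only = FALSE) {
  d <- merge(degs, classes, by = "gene_id")
  if (up_only) d <- d[d$direction == "up", , drop = FALSE]
  lv <- c("gain", "keep", "lose", "none")
  present <- lv[lv %in% d$class]
  if (length(present) < length(lv))
    warning("empty dynamics class(es) omitted: ",
            paste(setdiff(lv, present), collapse = ", "))
  groups <- split(d$log2fc, factor(d$class, levels = present))
  summary <- data.frame(class = present,
                        n = vapply(groups, length, integer(1)),
                        median_log2fc = vapply(groups, stats::median, numeric(1)),
                        mean_log2fc = vapply(groups, mean, numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  pairs <- if (length(present) >= 2) utils::combn(present, 2) else
    matrix(character(0), 2)
  tests <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                      p_value = apply(pairs, 2, function(pr)
                        wilcoxon_rank_sum(groups[[pr[1]]],
                                          groups[[pr[2]]])$p_value),
                      stringsAsFactors = FALSE)
  list(summary = summary, tests = tests)
}

#' Association between ZGA membership and m6A status among up-DEGs
#'
#' Builds the 2x2 contingency table of up-regulated DEGs (rows: ZGA /
#' non-ZGA; columns: m6A+ / m6A-), applies the two-tailed Fisher exact test,
#' and contrasts m6A intensity between m6A+ ZGA and m6A+ non-ZGA up-DEGs by
#' Wilcoxon rank-sum (when intensities are supplied).
#'
#' @param degs DEG table from [call_degs()].
#' @param status m6A status data.frame for the up-regulated condition.
#' @param zga_set character vector of ZGA gene ids (non-empty).
#' @param intensity optional data.frame (gene_id, intensity) for the
#'   intensity contrast.
#' @return List with \code{table} (2x2 matrix), \code{fisher}
#'   (p_value, odds_ratio) and optionally \code{intensity_contrast}.
#' @export
zga_m6a_association <- function(degs, status, zga_set, intensity = NULL) {
  stopifnot(length(zga_set) > 0)
  up <- degs$gene_id[degs$direction == "up"]
  if (length(up) == 0) stop("degenerate table: no up-regulated DEGs",
                            call. = FALSE)
  st <- stats::setNames(status$status, status$gene_id)[up]
  st[is.na(st)] <- FALSE
  is_zga <- up %in% zga_set
  tab <- matrix(c(sum(is_zga & st), sum(is_zga & !st),
                  sum(!is_zga & st), sum(!is_zga & !st)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("ZGA", "non-ZGA"), c("m6A+", "m6A-")))
  fis <- fisher_exact_2x2(tab)
  out <- list(table = tab, fisher = fis)
  if (!is.null(intensity)) {
    iv <- stats::setNames(intensity$intensity, intensity$gene_id)[up]
    a <- iv[is_zga & st]; b <- iv[!is_zga & st]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) >= 1 && length(b) >= 1)
      out$intensity_contrast <- c(wilcoxon_rank_sum(a, b),
                                  list(median_zga = stats::median(a),
                                       median_non_zga = stats::median(b)))
  }
  out
}

#' Top highly-expressed up-DEGs with ZGA and m6A annotation
#'
#' Filters up-regulated DEGs at FC > \code{fc_min}, ranks them by expression
#' in the target condition (descending, ties broken by gene_id) and returns
#' the top \code{n} with ZGA-membership and m6A-status flags.
#'
#' @param degs DEG table from [call_degs()].
#' @param status m6A status table for the target condition.
#' @param zga_set character vector of ZGA gene ids.
#' @param n number of rows returned (default 20; fewer if unavailable).
#' @param fc_min fold-change filter (default 3, strict).
#' @return data.frame: rank, gene_id, expression, log2fc, is_zga, m6a.
#' @export
top_updeg_annotation <- function(degs, status, zga_set, n = 20, fc_min = 3) {
  d <- degs[degs$direction == "up" & 2^degs$log2fc > fc_min, , drop = FALSE]
  d <- d[order(-d$mean_a, d$gene_id), , drop = FALSE]
  d <- utils::head(d, n)
  st <- stats::setNames(status$status, status$gene_id)[d$gene_id]
  st[is.na(st)] <- FALSE
  data.frame(rank = seq_len(nrow(d)), gene_id = d$gene_id,
             expression = d$mean_a, log2fc = d$log2fc,
             is_zga = d$gene_id %in% zga_set, m6a = unname(st),
             row.names = NULL, stringsAsFactors = FALSE)
}
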