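#' Relative expression by the delta-delta-Ct method
#'
#' \code{ddCt = (Ct_target - Ct_ref) - (Ct_target_cal - Ct_ref_cal)};
#' relative expression is \code{2^-ddCt}, i.e. target expression normalised
#' to a reference gene (e.g. GAPDH) and to a calibrator sample. Adding the
#' same number of cycles to both target Cts leaves the result unchanged.
#'
#' @param ct_target,ct_ref Ct values in the sample of interest.
#' @param ct_target_cal,ct_ref_cal Ct values in the calibrator sample.
#' @return Fold change \code{2^-ddCt}.
#' @examples
#' ddct_relative_expression(20, 18, 22, 18)  # ddCt = -2 -> fold 4
#' @export
ddct_relative_expression <- function(ct_target, ct_ref, ct_target_cal,
                                     ct_ref_cal) {
  vals <- c(ct_target, ct_ref, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(vals))) stop("non-finite Ct value", call. = FALSE)
  ddct <- (ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Fit first-order decay to a time course
#'
#' Models relative expression after transcription blockade as
#' \code{exp(-k t)}: least-squares fit of \code{ln(value) = -k t} with the
#' intercept fixed at 0 (values are normalised to 1 at t = 0 first), k
#' clipped at 0 and half-life \code{t1/2 = ln(2)/k} (infinite when k = 0).
#' Non-positive values are excluded with a warning. Scale-invariant:
#' multiplying all values by a constant changes nothing after the t = 0
#' normalisation.
#'
#' @param time hours, including 0; at least 2 distinct points.
#' @param value relative expression values (> 0).
#' @param free_intercept also estimate an intercept instead of forcing the
#'   course through 1 at t = 0 (non-default).
#' @return List with \code{k}, \code{half_life}, \code{r_squared},
#'   \code{se_k} (NA with < 3 usable points), \code{n_points}.
#' @export
fit_decay <- function(time, value, free_intercept = FALSE) {
  stopifnot(length(time) == length(value))
  o <- order(time)
  time <- time[o]; value <- value[o]
  if (any(value <= 0)) {
    warning("excluding ", sum(value <= 0), " non-positive value(s)")
    keep <- value > 0
    time <- time[keep]; value <- value[keep]
  }
  if (length(time) < 2 || length(unique(time)) < 2 || !any(time == 0))
    stop("unfittable course: need >= 2 usable time points including t = 0",
         call. = FALSE)
  value <- value / value[time == 0][1]
  lv <- log(value)
  if (free_intercept) {
    fit <- stats::lm(lv ~ time)
    k <- max(0, -unname(stats::coef(fit)[2]))
    se <- summary(fit)$coefficients[2, 2]
    res <- stats::residuals(fit)
  } else {
    k <- max(0, -sum(time * lv) / sum(time^2))
    res <- lv + k * time
    n <- length(time)
    se <- if (n >= 3) sqrt(sum(res^2) / (n - 1) / sum(time^2)) else NA_real_
  }
  sst <- sum((lv - mean(lv))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  list(k = k, half_life = if (k > 0) log(2) / k else Inf,
       r_squared = r2, se_k = se, n_points = length(time))
}

#' Fit decay courses from a tidy table
#'
#' @param courses data.frame with columns gene, condition, time_h, rel_expr.
#' @param ... passed to [fit_decay()].
#' @return data.frame: gene, condition, k, half_life, r_squared, se_k,
#'   n_points.
#' @export
fit_decay_table <- function(courses, ...) {
  out <- lapply(split(courses, list(courses$gene, courses$condition),
                      drop = TRUE), function(d) {
    f <- fit_decay(d$time_h, d$rel_expr, ...)
    data.frame(gene = d$gene[1], condition = d$condition[1], k = f$k,
               half_life = f$half_life, r_squared = f$r_squared,
               se_k = f$se_k, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare half-lives between conditions for m6A+ vs m6A- gene sets
#'
#' Per gene, the ratio \code{t1/2(inhibitor) / t1/2(ctrl)}; a stabilised
#' transcript has ratio > 1. Genes with infinite half-life in both
#' conditions get ratio 1 and are flagged. The m6A+ and m6A- sets' log
#' ratios are contrasted by Wilcoxon rank-sum — the readout for
#' "methyltransferase inhibition slows the decay of m6A-marked transcripts".
#'
#' @param fits data.frame from [fit_decay_table()] covering conditions
#'   \code{"ctrl"} and \code{"inhibitor"}.
#' @param set_m6a,set_non_m6a character gene sets.
#' @return List with \code{ratios} (gene, set, ratio, flagged),
#'   \code{median_m6a}, \code{median_non_m6a}, \code{p_value}.
#' @export
compare_half_life <- function(fits, set_m6a, set_non_m6a) {
  wide <- merge(fits[fits$condition == "ctrl", c("gene", "half_life")],
                fits[fits$condition == "inhibitor", c("gene", "half_life")],
                by = "gene", suffixes = c("_ctrl", "_inh"))
  both_inf <- is.infinite(wide$half_life_ctrl) & is.infinite(wide$half_life_inh)
  ratio <- wide$half_life_inh / wide$half_life_ctrl
  ratio[both_inf] <- 1
  df <- data.frame(gene = wide$gene, ratio = ratio, flagged = both_inf,
                   stringsAsFactors = FALSE)
  df$set <- ifelse(df$gene %in% set_m6a, "m6A+",
            ifelse(df$gene %in% set_non_m6a, "m6A-", NA))
  df <- df[!is.na(df$set), , drop = FALSE]
  a <- log(df$ratio[df$set == "m6A+"]); b <- log(df$ratio[df$set == "m6A-"])
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  list(ratios = df,
       median_m6a = stats::median(exp(a)),
       median_non_m6a = stats::median(exp(b)),
       p_value = if (length(a) >= 1 && length(b) >= 1)
         wilcoxon_rank_sum(a, b)$p_value else NA_real_)
}
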