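# Agreement and performance statistics for method comparison: model
# measurements against operator measurements, masks against masks.

#' Paired measurement series
#'
#' Equal-length measurements of the same subjects by two methods (e.g.
#' automated pipeline vs. operator).
#'
#' @param a,b numeric vectors of equal length (>= 2), finite.
#' @param ids optional subject identifiers.
#' @return Object of class `"paired_series"`.
#' @export
paired_series <- function(a, b, ids = seq_along(a)) {
  if (length(a) != length(b))
    fb_stop("fb_domain_error", "paired series must have equal length")
  if (length(a) < 2)
    fb_stop("fb_domain_error", "paired series needs at least 2 pairs")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    fb_stop("fb_domain_error", "paired series must be finite")
  structure(list(a = as.numeric(a), b = as.numeric(b), ids = ids,
                 n = length(a)),
            class = "paired_series")
}

#' Mean absolute error
#'
#' Mean and standard deviation of `|a_i - b_i|`.
#'
#' @param series a [paired_series()].
#' @return List with `mae`, `sd`, `n`.
#' @export
mae <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  ae <- abs(series$a - series$b)
  list(mae = mean(ae), sd = stats::sd(ae), n = series$n)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = a_i - b_i` (in percentage mode,
#' `100 (a_i - b_i) / ((a_i + b_i)/2)`, the pair mean being the standard
#' denominator for percentage limits); bias is the mean difference and the
#' 95% limits of agreement are `bias +/- 1.96 sd(d)` with the sample
#' (n-1) standard deviation. The 1.96 multiplier is a fixed constant of the
#' method, not a configurable z.
#'
#' @param series a [paired_series()].
#' @param percentage express differences as percentages of the pair mean.
#' @return Object of class `"agreement_stats"`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `percentage_mode`, `mae`, `n` (`icc` is filled
#'   by [icc()] when wanted).
#' @export
bland_altman <- function(series, percentage = FALSE) {
  stopifnot(inherits(series, "paired_series"))
  check_flag(percentage, "percentage")
  d <- series$a - series$b
  if (percentage) {
    m <- (series$a + series$b) / 2
    bad <- m == 0
    if (any(bad))
      fb_stop("fb_domain_error",
              "zero pair mean in percentage mode for subject(s): %s",
              paste(series$ids[bad], collapse = ", "))
    d <- 100 * d / m
  }
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 percentage_mode = percentage,
                 mae = mean(abs(series$a - series$b)),
                 icc = NA_real_, n = series$n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  u <- if (x$percentage_mode) "%" else ""
  cat(sprintf("Bland-Altman (n = %d): bias %.4g%s, 95%% LoA [%.4g, %.4g]%s\n",
              x$n, x$bias, u, x$loa_low, x$loa_high, u))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' Default is the one-way random-effects single-rater estimator ICC(1,1)
#' from the ANOVA mean squares, which for two raters reduces to
#' `(MSB - MSW) / (MSB + MSW)`; it estimates the between-subject share of
#' total variance \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)} and may be
#' negative in small samples. A two-way random-effects absolute-agreement
#' variant ICC(A,1) is available via `model = "twoway"`.
#'
#' @param series a [paired_series()] with at least 3 subjects.
#' @param model `"oneway"` (default) or `"twoway"`.
#' @return List with `icc`, `model`, `n`; when total variance is zero,
#'   `icc` is `NA` with a `reason`.
#' @export
icc <- function(series, model = c("oneway", "twoway")) {
  stopifnot(inherits(series, "paired_series"))
  model <- match.arg(model)
  n <- series$n
  if (n < 3) fb_stop("fb_domain_error", "ICC needs at least 3 subjects")
  x <- cbind(series$a, series$b)
  k <- 2
  subj_means <- rowMeans(x)
  grand <- mean(x)
  if (all(x == x[1]))
    return(list(icc = NA_real_, model = model, n = n,
                reason = "zero total variance"))
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((x - subj_means)^2) / (n * (k - 1))
  est <- if (model == "oneway") {
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    rater_means <- colMeans(x)
    msc <- n * sum((rater_means - grand)^2) / (k - 1)
    resid <- x - outer(subj_means, rep(1, k)) -
      outer(rep(1, n), rater_means) + grand
    mse <- sum(resid^2) / ((n - 1) * (k - 1))
    (msb - mse) / (msb + (k - 1) * mse + k / n * (msc - mse))
  }
  list(icc = est, model = model, n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (the original signed-rank convention) and
#' ties receive mid-ranks. The exact null distribution is used for up to 25
#' nonzero untied differences; otherwise the normal approximation with
#' continuity correction. All-zero differences are a degenerate outcome,
#' reported as such rather than as an error.
#'
#' @param series a [paired_series()]; at least 5 nonzero differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return List with `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `n_used`, `exact`.
#' @export
paired_wilcoxon <- function(series, exact_max = 25) {
  stopifnot(inherits(series, "paired_series"))
  d <- series$a - series$b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                exact = FALSE, reason = "all differences are zero"))
  if (length(d) < 5)
    fb_stop("fb_domain_error",
            "need at least 5 nonzero differences, have %d", length(d))
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- length(d) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, paired = FALSE,
                                            exact = use_exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = length(d), exact = use_exact)
}

#' Sensitivity and specificity
#'
#' Binary classification agreement with the full 2x2 table. When a class is
#' absent from the truth the corresponding metric is undefined and returned
#' as `NA` with a reason.
#'
#' @param pred,truth logical (or 0/1) vectors of equal length.
#' @return List with `sensitivity`, `specificity`, `table` (named counts
#'   TP/FP/TN/FN), and possibly `reason`.
#' @export
sens_spec <- function(pred, truth) {
  if (length(pred) != length(truth))
    fb_stop("fb_domain_error", "pred and truth must have equal length")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  out <- list(sensitivity = sens, specificity = spec,
              table = c(TP = tp, FP = fp, TN = tn, FN = fn))
  reasons <- c(if (is.na(sens)) "no positives in truth",
               if (is.na(spec)) "no negatives in truth")
  if (length(reasons)) out$reason <- paste(reasons, collapse = "; ")
  out
}

#' Dice and IoU mask overlap
#'
#' `dice = 2|A n B| / (|A| + |B|)`, `iou = |A n B| / |A u B|`. Two empty
#' masks agree perfectly by convention (both scores 1), documented here
#' because the 0/0 limit is otherwise undefined.
#'
#' @param mask_a,mask_b [label_mask()]s of equal dimensions.
#' @return List with `dice` and `iou`.
#' @export
dice_iou <- function(mask_a, mask_b) {
  stopifnot(inherits(mask_a, "label_mask"), inherits(mask_b, "label_mask"))
  if (!all(dim(mask_a$grid) == dim(mask_b$grid)))
    fb_stop("fb_domain_error", "mask dimensions differ")
  inter <- sum(mask_a$grid & mask_b$grid)
  a <- sum(mask_a$grid); b <- sum(mask_b$grid)
  union <- a + b - inter
  if (union == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (a + b), iou = inter / union)
}

#' Bland-Altman plot
#'
#' Pair means against differences with three horizontal lines: the bias and
#' the two limits of agreement.
#'
#' @param series a [paired_series()].
#' @param percentage percentage mode as in [bland_altman()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(series, percentage = FALSE, title = NULL) {
  stats <- bland_altman(series, percentage)
  m <- (series$a + series$b) / 2
  d <- series$a - series$b
  if (percentage) d <- 100 * d / m
  df <- data.frame(mean = m, diff = d)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = stats$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(stats$loa_low, stats$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Pair mean",
                  y = if (percentage) "Difference (%)" else "Difference",
                  title = title) +
    ggplot2::theme_minimal()
}
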