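# Agreement and variability statistics for nested (lesions-within-patient)
# dosimetry data: group-mean centering, centered correlations, Bland-Altman
# analysis, the Kruskal-Wallis between-patient test and a one-way
# random-effects intraclass correlation.

#' Group-mean-center values by patient
#'
#' Subtracts each patient's mean from that patient's values, removing
#' patient-level offsets so that lesion-level correlations are not inflated
#' by between-patient differences. Per-patient means of the output are zero;
#' centering is idempotent.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (patient ids) of the same length.
#' @return Centered numeric vector.
#' @examples
#' group_mean_center(c(1, 3, 10), c("a", "a", "b")) # -1, 1, 0
#' @export
group_mean_center <- function(values, group) {
  if (length(values) != length(group)) {
    stop("values and group must have equal length", call. = FALSE)
  }
  values - stats::ave(values, group, FUN = mean)
}

#' Correlation of group-mean-centered data
#'
#' Centers `x` and `y` within patients and computes the Pearson
#' product-moment correlation (or Spearman's rank correlation: average ranks
#' taken after centering) of the centered data. Because centering removes one
#' dimension per patient, the two-sided p-value uses the t approximation with
#' `n - g - 1` degrees of freedom, where `g` is the number of patients; this
#' keeps the test calibrated under the null for nested data.
#'
#' @param x,y Numeric vectors (one value per lesion).
#' @param group Patient ids.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `estimate`, `p_value`, `df`, `n`, `n_groups`, `method`.
#'   `estimate` and `p_value` are `NA` when a centered variable has zero
#'   variance.
#' @export
centered_correlation <- function(x, y, group, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) != length(group)) {
    stop("x, y and group must have equal length", call. = FALSE)
  }
  n <- length(x)
  g <- length(unique(group))
  df <- n - g - 1
  if (df < 1) stop("need at least n_groups + 2 observations", call. = FALSE)
  cx <- group_mean_center(x, group)
  cy <- group_mean_center(y, group)
  if (method == "spearman") {
    cx <- rank(cx, ties.method = "average")
    cy <- rank(cy, ties.method = "average")
  }
  if (stats::sd(cx) == 0 || stats::sd(cy) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_, df = df, n = n,
                n_groups = g, method = method))
  }
  r <- stats::cor(cx, cy)
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(estimate = r, p_value = p, df = df, n = n, n_groups = g, method = method)
}

#' Bland-Altman agreement of predicted and measured doses
#'
#' Differences are taken as `predicted - measured` (a positive bias means the
#' prediction over-estimates the delivered dose). Returns the bias, the
#' sample standard deviation of the differences, the 95% limits of agreement
#' `bias +/- 1.96 sd`, and the per-pair relative percentage differences
#' `100 * (measured - predicted) / predicted` with their median.
#'
#' @param predicted,measured Numeric vectors of paired doses (Gy).
#' @return An object of class `agreement_summary`: `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`, `relative_diff_percent` (vector) and
#'   `median_relative_diff_percent`.
#' @examples
#' bland_altman(c(10, 20), c(5, 15)) # bias 5, sd 0
#' @export
bland_altman <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    stop("predicted and measured must have equal length", call. = FALSE)
  }
  if (length(predicted) < 2L) stop("at least two pairs are required", call. = FALSE)
  d <- predicted - measured
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  rel <- ifelse(predicted > 0, 100 * (measured - predicted) / predicted, NA_real_)
  structure(
    list(
      bias = bias,
      sd_diff = sd_diff,
      loa_lower = bias - 1.96 * sd_diff,
      loa_upper = bias + 1.96 * sd_diff,
      n = length(d),
      relative_diff_percent = rel,
      median_relative_diff_percent = stats::median(rel, na.rm = TRUE)
    ),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> n = %d: bias = %.4g (sd %.4g), LoA [%.4g, %.4g], median relative diff = %.3g%%\n",
    x$n, x$bias, x$sd_diff, x$loa_lower, x$loa_upper,
    x$median_relative_diff_percent
  ))
  invisible(x)
}

#' Kruskal-Wallis test of between-patient differences
#'
#' Rank-based test (with tie correction) of whether the distribution of a
#' lesion-level quantity differs between patients; `df = groups - 1`, p-value
#' from the chi-squared approximation. Thin wrapper over
#' [stats::kruskal.test()] returning a plain list.
#'
#' @param values Numeric vector (one value per lesion).
#' @param group Patient ids.
#' @return A list: `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, group) {
  if (length(values) != length(group)) {
    stop("values and group must have equal length", call. = FALSE)
  }
  if (length(unique(group)) < 2L) stop("need at least two groups", call. = FALSE)
  if (stats::var(values) == 0) {
    return(list(H = 0, df = length(unique(group)) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, factor(group))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Intraclass correlation from one-way random-effects variance components
#'
#' Method-of-moments estimator for the share of variance attributable to
#' between-patient differences, using the unbalanced one-way ANOVA
#' formulation: `sigma2_w = MSW`, `sigma2_b = (MSB - MSW) / n0` with
#' `n0 = (N - sum(n_i^2)/N) / (g - 1)`, negative component estimates
#' truncated at zero, and `ICC = sigma2_b / (sigma2_b + sigma2_w)`.
#'
#' @param values Numeric vector (one value per lesion).
#' @param group Patient ids.
#' @return A list: `icc`, `sigma2_between`, `sigma2_within`, `n`, `n_groups`.
#' @export
icc_patients <- function(values, group) {
  if (length(values) != length(group)) {
    stop("values and group must have equal length", call. = FALSE)
  }
  group <- factor(group)
  g <- nlevels(group)
  n <- length(values)
  if (g < 2L || n < g + 1L) {
    stop("ICC requires at least two patients and more lesions than patients",
         call. = FALSE)
  }
  ni <- as.vector(table(group))
  means <- tapply(values, group, mean)
  grand <- mean(values)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((values - means[group])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  n0 <- (n - sum(ni^2) / n) / (g - 1)
  sigma2_b <- max((msb - msw) / n0, 0)
  sigma2_w <- msw
  denom <- sigma2_b + sigma2_w
  icc <- if (denom > 0) sigma2_b / denom else 0
  list(icc = icc, sigma2_between = sigma2_b, sigma2_within = sigma2_w,
       n = n, n_groups = g)
}

#' Pair predicted and measured doses by lesion
#'
#' Joins a predicted-dose table and a measured-dose table on `lesion_id` and
#' computes the relative percentage difference
#' `100 * (measured - predicted) / predicted` per lesion.
#'
#' @param predicted,measured Data frames with `lesion_id`, `patient_id`,
#'   `dose_Gy`.
#' @return Data frame: `lesion_id`, `patient_id`, `predicted_Gy`,
#'   `measured_Gy`, `relative_diff_percent`.
#' @export
theranostic_pairs <- function(predicted, measured) {
  idx <- match(predicted$lesion_id, measured$lesion_id)
  keep <- !is.na(idx)
  data.frame(
    lesion_id = predicted$lesion_id[keep],
    patient_id = predicted$patient_id[keep],
    predicted_Gy = predicted$dose_Gy[keep],
    measured_Gy = measured$dose_Gy[idx[keep]],
    relative_diff_percent = 100 *
      (measured$dose_Gy[idx[keep]] - predicted$dose_Gy[keep]) /
      predicted$dose_Gy[keep],
    stringsAsFactors = FALSE
  )
}
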