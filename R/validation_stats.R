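#' Combine independent error components by root-sum-square
#'
#' The total error is the square root of the squared sum of all contributing
#' errors. The result is permutation-invariant, homogeneous of degree 1 and
#' never smaller than the largest component.
#'
#' @param components Non-negative numeric vector of error components (all in
#'   the same units, or all in percent).
#' @return Combined error, same units.
#' @export
combine_errors <- function(components) {
  components <- as.numeric(components)
  if (anyNA(components) || any(components < 0))
    stop("error components must be non-negative numbers", call. = FALSE)
  sqrt(sum(components^2))
}

#' Reproducibility variation across repeated estimates
#'
#' For each subject, the mean absolute deviation of the repeated estimates
#' from the subject mean, expressed in percent of that mean; then averaged
#' over subjects. This is the VOI-choice reproducibility statistic: each
#' "repeat" is the estimate recomputed with an alternative VOI combination.
#'
#' @param estimates A list with one numeric vector of repeated estimates per
#'   subject (each of length >= 2), or a single numeric vector for one
#'   subject.
#' @return Mean reproducibility variation in percent.
#' @export
reproducibility_variation <- function(estimates) {
  if (is.numeric(estimates)) estimates <- list(estimates)
  per_subject <- vapply(estimates, function(x) {
    x <- as.numeric(x)
    if (length(x) < 2) stop("need at least 2 repeats per subject", call. = FALSE)
    m <- mean(x)
    if (m == 0) stop("subject mean is zero; percent deviation undefined", call. = FALSE)
    100 * mean(abs(x - m)) / abs(m)
  }, numeric(1))
  mean(per_subject)
}

#' Method-agreement analysis (Pearson, paired t, Bland-Altman)
#'
#' Computes the Pearson product-moment correlation with its two-sided
#' p-value, a paired Student's t test, and the Bland-Altman difference
#' statistics: mean difference, SD of the differences, and agreement limits
#' at mean +/- 2 SD.
#'
#' @param a,b Paired numeric vectors of equal length >= 3 (e.g. FDG-derived
#'   and reference values).
#' @param diff_sign Sign convention for the Bland-Altman difference:
#'   `"a_minus_b"` (default) or `"b_minus_a"`.
#' @return An object of class `agreement_report` with `pearson_r`,
#'   `p_value`, `paired_t_p`, `ba_mean_diff`, `ba_sd_diff`, `ba_limits`
#'   (length-2 vector), `n`.
#' @export
agreement_analysis <- function(a, b, diff_sign = c("a_minus_b", "b_minus_a")) {
  diff_sign <- match.arg(diff_sign)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must be paired", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values in paired series", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one series; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  d <- if (diff_sign == "a_minus_b") a - b else b - a
  tt_p <- if (stats::sd(d) == 0) 1 else stats::t.test(a, b, paired = TRUE)$p.value
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 paired_t_p = tt_p, ba_mean_diff = md, ba_sd_diff = sdd,
                 ba_limits = c(md - 2 * sdd, md + 2 * sdd),
                 diff_sign = diff_sign, n = length(a)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement (n=%d): r = %.3f (p = %.2g), paired-t p = %.2g\n",
              x$n, x$pearson_r, x$p_value, x$paired_t_p))
  cat(sprintf("  Bland-Altman (%s): %.3g +/- %.3g, limits [%.3g, %.3g]\n",
              x$diff_sign, x$ba_mean_diff, x$ba_sd_diff,
              x$ba_limits[1], x$ba_limits[2]))
  invisible(x)
}

#' Normality screen (one-sample Kolmogorov-Smirnov)
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD. Estimating the parameters from the same sample makes
#' the p-value conservative (Lilliefors caveat); the test is intended as a
#' screen before parametric statistics, not as a calibrated test.
#'
#' @param values Numeric vector, length >= 5, non-degenerate.
#' @return List with `statistic` (KS D) and `p_value`.
#' @export
normality_screen <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
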