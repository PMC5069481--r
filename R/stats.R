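#' Homeostasis-model insulin-resistance index
#'
#' HOMA-IR = (FBG x FPI) / 405, with fasting blood glucose in mg/dL and
#' fasting plasma insulin in mU/L; the factor 405 accounts for the units.
#'
#' @param fbg_mg_dl fasting blood glucose (mg/dL), >= 0.
#' @param fpi_mU_L fasting plasma insulin (mU/L), >= 0.
#' @return The HOMA-IR index.
#' @export
homa_ir <- function(fbg_mg_dl, fpi_mU_L) {
  if (any(fbg_mg_dl < 0) || any(fpi_mU_L < 0)) stop("inputs must be non-negative")
  fbg_mg_dl * fpi_mU_L / 405
}

# round half away from zero, as in reported percentages
round_half_away <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Percent difference of a test mean relative to a reference mean
#'
#' @param test_mean,ref_mean group means; `ref_mean` must be non-zero.
#' @return `100 * (test_mean - ref_mean) / ref_mean`, rounded to one
#'   decimal (half away from zero), as percentages are reported.
#' @export
percent_difference <- function(test_mean, ref_mean) {
  if (any(ref_mean == 0)) stop("reference mean must be non-zero")
  round_half_away(100 * (test_mean - ref_mean) / ref_mean, 1)
}

#' Fold change of a test mean relative to a reference mean
#'
#' Consistent with [percent_difference()]: before rounding,
#' `fold == 1 + pct/100` exactly.
#'
#' @param test_mean,ref_mean group means; `ref_mean` must be positive.
#' @return `test_mean / ref_mean`, rounded to one decimal.
#' @export
fold_change <- function(test_mean, ref_mean) {
  if (any(ref_mean <= 0)) stop("reference mean must be positive")
  round_half_away(test_mean / ref_mean, 1)
}

# two-sided Dixon Q critical values (r10 ratio), alpha = 0.05, n = 3..30
dixon_crit_05 <- c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
                   0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
                   0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
                   0.308, 0.305, 0.301, 0.298)

#' Dixon Q outlier screen
#'
#' Two-sided Dixon ratio test (r10): Q = gap/range for the smallest and the
#' largest value, compared against the classical alpha = 0.05 critical
#' value for the sample size. At most the single most extreme value is
#' flagged; constant samples have zero range and are never flagged.
#'
#' @param values numeric vector, 3 <= n <= 30.
#' @return A list: `flags` (logical, same length as `values`), `q_low`,
#'   `q_high`, `critical`.
#' @export
dixon_q <- function(values) {
  n <- length(values)
  if (n < 3 || n > 30) stop("Dixon test requires 3 <= n <= 30")
  s <- sort(values)
  rng <- s[n] - s[1]
  flags <- rep(FALSE, n)
  if (rng == 0)
    return(list(flags = flags, q_low = 0, q_high = 0,
                critical = dixon_crit_05[n - 2]))
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  crit <- dixon_crit_05[n - 2]
  if (max(q_low, q_high) > crit) {
    if (q_high >= q_low) flags[which.max(values)] <- TRUE
    else flags[which.min(values)] <- TRUE
  }
  list(flags = flags, q_low = q_low, q_high = q_high, critical = crit)
}

#' Two-group comparison following the normality-driven decision flow
#'
#' Applies the decision flow used for small-n animal group comparisons:
#' Shapiro-Wilk normality on each group (alpha 0.05). If both groups are
#' normal, equality of variances is tested with the F test and a two-tailed
#' unpaired t test is used (pooled when variances are equal, Welch
#' otherwise). If either group is non-normal, Levene's test is reported for
#' the variances and a Kruskal-Wallis test is used. A Dixon outlier screen
#' is reported for each group but never removes data.
#'
#' @param a,b numeric vectors (n >= 3 each); `b` is the reference group for
#'   the relative difference.
#' @param labels optional `c(name_a, name_b)`.
#' @return A list of class `comparison_report`: `test_used`
#'   (`"t_equal_var"`, `"t_unequal_var"` or `"kruskal_wallis"`), `p_value`,
#'   `normal` (per-group Shapiro p and flags), `variance_equal` flag and
#'   p value, `outlier_flags`, `means`, `sds`, `relative_difference_pct`.
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  if (length(a) < 3 || length(b) < 3)
    stop("need n >= 3 per group for the normality screen")
  sw_a <- stats::shapiro.test(a)$p.value
  sw_b <- stats::shapiro.test(b)$p.value
  normal <- sw_a > 0.05 && sw_b > 0.05
  if (normal) {
    vt <- stats::var.test(a, b)
    equal_var <- vt$p.value > 0.05
    tt <- stats::t.test(a, b, var.equal = equal_var)
    test_used <- if (equal_var) "t_equal_var" else "t_unequal_var"
    p <- tt$p.value
    var_p <- vt$p.value
  } else {
    g <- factor(rep(labels, c(length(a), length(b))))
    lev <- car::leveneTest(c(a, b), g, center = mean)
    var_p <- lev[["Pr(>F)"]][1]
    equal_var <- var_p > 0.05
    kw <- stats::kruskal.test(list(a, b))
    test_used <- "kruskal_wallis"
    p <- kw$p.value
  }
  structure(list(
    test_used = test_used,
    p_value = p,
    normal = list(p = c(sw_a, sw_b), flag = c(sw_a > 0.05, sw_b > 0.05)),
    variance_equal = equal_var,
    variance_p = var_p,
    outlier_flags = list(dixon_q(a)$flags, dixon_q(b)$flags),
    means = stats::setNames(c(mean(a), mean(b)), labels),
    sds = stats::setNames(c(stats::sd(a), stats::sd(b)), labels),
    relative_difference_pct = percent_difference(mean(a), mean(b))),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("%s: p = %.4g; means %s; rel. diff %.1f%%\n",
              x$test_used, x$p_value,
              paste(sprintf("%s = %.3g +/- %.3g", names(x$means), x$means,
                            x$sds), collapse = ", "),
              x$relative_difference_pct))
  invisible(x)
}

#' Paired comparison of matched per-specimen metrics at two resolutions
#'
#' Paired t test on matched specimen values (e.g. the same bones analyzed
#' at 2 um and 1 um voxel size), with the relative difference of the coarse
#' scan reported against the fine scan:
#' `100 * (mean(m2) - mean(m1)) / mean(m1)`.
#'
#' @param m1 per-specimen values at the reference (fine) resolution.
#' @param m2 matched values at the test (coarse) resolution, same order.
#' @return A list of class `paired_report`: `p_value` (`NA`, flagged, when
#'   the differences are constant), `relative_difference_pct`,
#'   `mean_difference`, `n`.
#' @export
paired_resolution_compare <- function(m1, m2) {
  if (length(m1) != length(m2)) stop("matched vectors must have equal length")
  keep <- !is.na(m1) & !is.na(m2)
  m1 <- m1[keep]
  m2 <- m2[keep]
  d <- m2 - m1
  degenerate <- length(d) < 2 || stats::sd(d) == 0
  p <- if (degenerate) NA_real_ else stats::t.test(m2, m1, paired = TRUE)$p.value
  structure(list(p_value = p,
                 degenerate = degenerate,
                 relative_difference_pct =
                   if (length(d) > 0) 100 * (mean(m2) - mean(m1)) / mean(m1)
                   else NA_real_,
                 mean_difference = if (length(d) > 0) mean(d) else NA_real_,
                 n = length(d)),
            class = "paired_report")
}

#' @export
print.paired_report <- function(x, ...) {
  cat(sprintf("paired t: p = %s, relative difference %.1f%% (n = %d)\n",
              ifelse(is.na(x$p_value), "NA (constant differences)",
                     sprintf("%.4g", x$p_value)),
              x$relative_difference_pct, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input")
  stats::cor(x, y)
}
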