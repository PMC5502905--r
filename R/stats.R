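## Agreement and group-discrimination statistics: Pearson correlation,
## Bland-Altman limits of agreement, Student t test, ROC / AUC with the
## Youden-optimal cutoff, chi-square on the large-core rule, two-way
## absolute-agreement ICC with F-based confidence bounds, within-subject
## coefficient of variation, and Cohen's kappa.

#' Pearson product-moment correlation with two-sided p value
#'
#' @param x,y Paired numeric vectors, n >= 3, nonzero variance.
#' @return A list: `r`, `p` (t transform with n - 2 df), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop2("'x' and 'y' must be paired")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop2("at least 3 finite pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("zero variance in ", if (stats::sd(x) == 0) "'x'" else "'y'")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `measured - reference`; the bias is their mean and the
#' 95\% limits of agreement are bias +/- 1.96 times their sample standard
#' deviation.
#'
#' @param measured,reference Paired measurements (here: lipid area \%).
#' @return A list: `bias`, `loa_low`, `loa_high`, `sd_diff`, `differences`,
#'   `means` (pairwise averages, the conventional x axis).
#' @export
bland_altman <- function(measured, reference) {
  if (length(measured) != length(reference)) stop2("inputs must be paired")
  if (length(measured) < 2L) stop2("at least 2 pairs are required")
  d <- measured - reference
  bias <- mean(d)
  s <- stats::sd(d)
  if (!is.finite(s)) s <- 0
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, differences = d, means = (measured + reference) / 2)
}

#' Relative difference between two group means
#'
#' `(a - b) / b * 100`, in percent of the reference mean `b`.
#'
#' @param group_a_mean,group_b_mean Group means; `group_b_mean` must be
#'   nonzero.
#' @return Relative difference in percent.
#' @examples
#' relative_difference(31.5, 15.8)  # 99.4
#' @export
relative_difference <- function(group_a_mean, group_b_mean) {
  check_number(group_a_mean, "group_a_mean")
  check_number(group_b_mean, "group_b_mean")
  if (group_b_mean == 0) stop2("reference mean must be nonzero")
  (group_a_mean - group_b_mean) / group_b_mean * 100
}

#' Two-sample Student t test with group summaries
#'
#' Pooled-variance two-sided test by default (Welch available); group means
#' are reported with standard errors of the mean.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param welch If `TRUE`, use the Welch unequal-variance test.
#' @return A list: `t`, `p`, `df`, `mean_a`, `sem_a`, `mean_b`, `sem_b`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop2("each group needs n >= 2")
  tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
       mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)))
}

#' ROC analysis of a continuous score against binary labels
#'
#' The AUC uses the Mann-Whitney rank formulation (ties count one half);
#' the curve is traced over all unique-score cutpoints with the calling
#' convention that a score greater than or equal to the cutoff calls the
#' case positive (symptomatic). The optimal cutoff maximizes Youden's
#' J = sensitivity + specificity - 1; among maximizers the lowest cutoff is
#' returned.
#'
#' @param scores Numeric scores (here: plaque lipid area \%).
#' @param labels Logical (or 0/1) case labels; both classes must be present.
#' @return A list: `auc`, `curve` (data.frame `cutoff`, `sensitivity`,
#'   `specificity`), `optimal_cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop2("'scores' and 'labels' must be paired")
  if (!any(labels) || all(labels))
    stop2("both classes must be present for ROC analysis")
  pos <- scores[labels]; neg <- scores[!labels]
  ## Mann-Whitney AUC via midranks: U / (n_pos * n_neg)
  rk <- rank(c(pos, neg))
  auc <- (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  cuts <- c(sort(unique(scores)), Inf)
  sens <- vapply(cuts, function(cf) mean(pos >= cf), 0)
  spec <- vapply(cuts, function(cf) mean(neg < cf), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(cuts[best])]
  list(auc = auc,
       curve = data.frame(cutoff = cuts, sensitivity = sens,
                          specificity = spec),
       optimal_cutoff = cuts[best], sensitivity = sens[best],
       specificity = spec[best], youden_j = j[best],
       n_pos = length(pos), n_neg = length(neg))
}

#' Chi-square test of the large-core rule against symptom status
#'
#' Cross-tabulates symptom status against "large core" (lipid area at or
#' above the cutoff, inclusive) and applies the Pearson chi-square test,
#' without continuity correction by default.
#'
#' @param summaries `data.frame` with `mean_lipid_area_pct` and
#'   `symptomatic` columns (one row per plaque).
#' @param cutoff Large-core cutoff in percent (inclusive, default 25).
#' @param correct If `TRUE`, apply the Yates continuity correction.
#' @return A list: `chi2`, `p`, `table` (2 x 2 counts), `cutoff`.
#' @export
chi2_large_lrnc <- function(summaries, cutoff = 25, correct = FALSE) {
  if (!all(c("mean_lipid_area_pct", "symptomatic") %in% names(summaries)))
    stop2("'summaries' needs 'mean_lipid_area_pct' and 'symptomatic' columns")
  sym <- as.logical(summaries$symptomatic)
  if (!any(sym) || all(sym)) stop2("both symptom classes must be present")
  large <- summaries$mean_lipid_area_pct >= cutoff
  tab <- table(factor(sym, c(TRUE, FALSE), c("symptomatic", "asymptomatic")),
               factor(large, c(TRUE, FALSE), c("large_core", "small_core")))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab,
       cutoff = cutoff)
}

#' Intraclass correlation coefficient for scan-rescan agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1) in the McGraw-Wong taxonomy) computed from the two-way ANOVA
#' mean squares, with the standard F-distribution confidence bounds.
#'
#' @param a,b Paired measurements (scan A and scan B) per subject, n >= 3.
#' @param conf_level Confidence level for the interval.
#' @return A list: `icc`, `ci_low`, `ci_high`, `ms` (mean squares),
#'   `degenerate` (`TRUE` when between-subject variance is zero).
#' @export
icc_absolute <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop2("'a' and 'b' must be paired")
  n <- length(a)
  if (n < 3L) stop2("at least 3 subject pairs are required")
  k <- 2L
  X <- cbind(a, b)
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  msr <- k * sum((row_m - grand)^2) / (n - 1)            # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)            # scans
  sse <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                ms = c(msr = msr, msc = msc, mse = mse), degenerate = TRUE))
  icc <- (msr - mse) / denom
  ## between-subject variance estimate (msr - mse) / k at or below zero
  degenerate <- msr <= mse
  ## F-based interval (McGraw & Wong) with Satterthwaite df for the
  ## between-column component.
  alpha <- 1 - conf_level
  a_c <- k * icc / (n * (1 - icc))
  b_c <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (!is.finite(a_c) || !is.finite(b_c)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    v <- (a_c * msc + b_c * mse)^2 /
      ((a_c * msc)^2 / (k - 1) + (b_c * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2],
       ms = c(msr = msr, msc = msc, mse = mse), degenerate = degenerate)
}

#' Within-subject coefficient of variation for paired replicates
#'
#' The within-subject standard deviation is `sqrt(mean(d^2) / 2)` over the
#' pair differences `d`; the CoV divides it by the grand mean, in percent.
#'
#' @param a,b Paired measurements per subject, n >= 2.
#' @return CoV in percent.
#' @export
cov_within <- function(a, b) {
  if (length(a) != length(b)) stop2("'a' and 'b' must be paired")
  if (length(a) < 2L) stop2("at least 2 pairs are required")
  gm <- mean(c(a, b))
  if (gm == 0) stop2("grand mean is zero; CoV undefined")
  sw <- sqrt(mean((a - b)^2) / 2)
  100 * sw / gm
}

#' Cohen's kappa and observed agreement for a confusion matrix
#'
#' `p_o` is the diagonal fraction, `p_e` the chance agreement from the row
#' and column margins, and `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param confusion Square non-negative count matrix (rows: reference,
#'   columns: predicted).
#' @return A list: `kappa`, `agreement_pct` (observed agreement in
#'   percent), `p_observed`, `p_expected`, `n`.
#' @examples
#' tab <- matrix(c(7, 1, 1, 0,  2, 7, 0, 0,  0, 0, 4, 0,  0, 0, 1, 3), 4, 4)
#' cohens_kappa(tab)
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop2("'confusion' must be square (reference x predicted)")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop2("'confusion' must hold non-negative integer counts")
  n <- sum(confusion)
  if (n < 1) stop2("'confusion' must contain at least one observation")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) {
    if (po == 1) kappa <- 1
    else stop2("degenerate table: chance agreement is 1 but observed agreement is not")
  } else kappa <- (po - pe) / (1 - pe)
  list(kappa = kappa, agreement_pct = 100 * po, p_observed = po,
       p_expected = pe, n = n)
}

#' Full agreement report between measured and reference lipid areas
#'
#' @param measured,reference Paired lipid area percentages.
#' @return A list combining [pearson_r()], [bland_altman()] and the RMSE.
#' @export
agreement_report <- function(measured, reference) {
  pr <- pearson_r(measured, reference)
  ba <- bland_altman(measured, reference)
  list(r = pr$r, p = pr$p, n = pr$n, bias = ba$bias,
       loa_low = ba$loa_low, loa_high = ba$loa_high,
       rmse_pct = sqrt(mean((measured - reference)^2)))
}
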