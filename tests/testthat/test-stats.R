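test_that("pearson correlation handles exact, null and degenerate inputs", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "3 finite pairs")

  set.seed(5)
  big <- pearson_r(runif(1e4), runif(1e4))
  expect_lt(abs(big$r), 0.05)

  # p value equals the n-2 df t transform
  set.seed(6)
  a <- rnorm(20); b <- a + rnorm(20)
  pr <- pearson_r(a, b)
  tstat <- pr$r * sqrt(18 / (1 - pr$r^2))
  expect_equal(pr$p, 2 * pt(-abs(tstat), 18), tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits follow their closed forms", {
  m <- c(10, 20, 30)
  expect_equal(bland_altman(m, m)[c("bias", "loa_low", "loa_high")],
               list(bias = 0, loa_low = 0, loa_high = 0))

  ba <- bland_altman(c(9, 21), c(10, 20))   # differences -1, +1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)

  # bias + mean(reference) = mean(measured), exactly
  set.seed(7)
  meas <- runif(40, 0, 50); ref <- runif(40, 0, 50)
  ba2 <- bland_altman(meas, ref)
  expect_equal(ba2$bias + mean(ref), mean(meas), tolerance = 1e-12)

  # consistency: the bias estimates a known offset
  set.seed(8)
  ref3 <- runif(4000, 10, 40)
  ba3 <- bland_altman(ref3 + 2.5 + rnorm(4000), ref3)
  expect_lt(abs(ba3$bias - 2.5), 0.1)
})

test_that("relative differences reproduce the worked examples", {
  expect_equal(round(relative_difference(31.5, 15.8), 1), 99.4)
  expect_equal(round(relative_difference(128.0, 105.6), 1), 21.2)
  expect_equal(relative_difference(7, 7), 0)
  expect_error(relative_difference(1, 0), "nonzero")
})

test_that("t test separates shifted groups and is calibrated under the null", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_lt(two_sample_t(c(1, 2, 3), c(101, 102, 103))$p, 1e-6)

  sem <- two_sample_t(c(2, 4, 6), c(1, 1, 1))
  expect_equal(sem$sem_a, sd(c(2, 4, 6)) / sqrt(3))

  # matches the standard pooled and Welch implementations
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 0.3)
  expect_equal(two_sample_t(a, b)$p, t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(a, b, welch = TRUE)$p, t.test(a, b)$p.value)

  # type-I error at the nominal level over a large null simulation
  set.seed(10)
  rejections <- 0L
  for (i in 1:10000) {
    x <- rnorm(10); y <- rnorm(12)
    if (two_sample_t(x, y)$p < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / 10000 - 0.05), 0.01)
})

test_that("ROC analysis matches the pairwise-count oracle and the null", {
  # perfect separation
  perf <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)

  # brute-force pairwise count on random small instances (with ties)
  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(1:8, n, replace = TRUE)
    roc <- roc_analysis(scores, labels)
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
    # curve points are honest empirical rates
    j <- which.max(roc$curve$sensitivity + roc$curve$specificity)
    expect_equal(roc$youden_j,
                 max(roc$curve$sensitivity + roc$curve$specificity) - 1,
                 tolerance = 1e-12)
  }

  # agreement with an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- rnorm(40); lb <- runif(40) > 0.5
  expect_equal(roc_analysis(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)

  # null: labels independent of scores
  set.seed(13)
  aucs <- vapply(1:1000, function(i)
    roc_analysis(rnorm(24), rep(c(TRUE, FALSE), 12))$auc, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("large-core chi-square uses the inclusive 25% rule", {
  # hand formula for [[10,5],[1,10]]: n (ad - bc)^2 / (r1 r2 c1 c2)
  df <- data.frame(
    mean_lipid_area_pct = c(rep(30, 10), rep(10, 5), rep(30, 1), rep(10, 10)),
    symptomatic = c(rep(TRUE, 15), rep(FALSE, 11)))
  out <- chi2_large_lrnc(df)
  expect_equal(unname(out$table["symptomatic", "large_core"]), 10)
  hand <- 26 * (10 * 10 - 5 * 1)^2 / (15 * 11 * 11 * 15)
  expect_equal(out$chi2, hand, tolerance = 1e-12)

  # independence gives chi2 = 0
  bal <- data.frame(mean_lipid_area_pct = rep(c(30, 10), 10),
                    symptomatic = rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  expect_equal(chi2_large_lrnc(bal)$chi2, 0, tolerance = 1e-12)

  # exactly 25% counts as large
  edge <- data.frame(mean_lipid_area_pct = c(25, 10, 25, 10, 25, 10),
                     symptomatic = c(T, T, T, F, F, F))
  expect_identical(unname(chi2_large_lrnc(edge)$table[, "large_core"]),
                   c(2L, 1L))
})

test_that("absolute-agreement ICC matches ANOVA mean squares and hand work", {
  a <- c(10, 20, 30, 40)
  expect_equal(icc_absolute(a, a)$icc, 1)

  # hand-worked toy table
  b <- c(12, 19, 33, 38)
  out <- icc_absolute(a, b)
  X <- cbind(a, b); n <- 4; k <- 2
  grand <- mean(X)
  msr <- k * sum((rowMeans(X) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(X) - grand)^2) / (k - 1)
  mse <- (sum((X - outer(rowMeans(X), rep(1, k)) -
                 outer(rep(1, n), colMeans(X)) + grand)^2)) / ((n - 1) * (k - 1))
  hand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(out$icc, hand, tolerance = 1e-12)

  # mean squares agree with a two-way ANOVA fit
  long <- data.frame(y = c(a, b), subj = factor(rep(1:4, 2)),
                     scan = factor(rep(1:2, each = 4)))
  av <- summary(aov(y ~ subj + scan, data = long))[[1]]
  expect_equal(unname(out$ms["msr"]), av["subj", "Mean Sq"], tolerance = 1e-9)
  expect_equal(unname(out$ms["msc"]), av["scan", "Mean Sq"], tolerance = 1e-9)
  expect_equal(unname(out$ms["mse"]), av["Residuals", "Mean Sq"],
               tolerance = 1e-9)

  # noise-dominated pairs give near-zero ICC
  set.seed(14)
  iccs <- vapply(1:100, function(i) {
    s <- rnorm(10, 20, 0.5)
    icc_absolute(s + rnorm(10, 0, 10), s + rnorm(10, 0, 10))$icc
  }, 0)
  expect_lt(abs(mean(iccs)), 0.12)

  # known variance ratio is recovered on average
  set.seed(15)
  iccs2 <- vapply(1:200, function(i) {
    subj <- rnorm(30, 25, 4)       # var 16
    icc_absolute(subj + rnorm(30, 0, 2), subj + rnorm(30, 0, 2))$icc
  }, 0)
  expect_lt(abs(mean(iccs2) - 16 / 20), 0.04)

  expect_error(icc_absolute(1:2, 2:1), "at least 3")
  expect_true(icc_absolute(c(5, 5, 5), c(5, 5, 5) + 1e-9)$degenerate ||
                icc_absolute(c(5, 5, 5), c(5, 5, 5) + 1e-9)$icc < 1)
})

test_that("within-subject CoV follows the paired-difference definition", {
  expect_equal(cov_within(c(10, 20, 30), c(10, 20, 30)), 0)

  a <- c(10, 20, 30, 10); b <- c(10, 20, 30, 12)
  sw <- sqrt(mean((a - b)^2) / 2)
  expect_equal(cov_within(a, b), 100 * sw / mean(c(a, b)), tolerance = 1e-12)

  # scale invariance
  expect_equal(cov_within(3 * a, 3 * b), cov_within(a, b), tolerance = 1e-12)
  expect_error(cov_within(c(1, -1), c(-1, 1)), "grand mean")
})

test_that("Cohen's kappa reproduces the published plaque-type agreement", {
  tab <- matrix(c(7, 1, 1, 0,
                  2, 7, 0, 0,
                  0, 0, 4, 0,
                  0, 0, 1, 3), 4, 4)  # rows: histology IV-V, VI, VII, VIII
  out <- cohens_kappa(tab)
  expect_equal(round(out$kappa, 2), 0.73)
  expect_equal(round(out$agreement_pct, 1), 80.8)

  expect_equal(cohens_kappa(diag(5))$kappa, 1)

  # independence construction: mass spread proportional to the margins
  ind <- outer(c(12, 6), c(12, 6)) / 18
  expect_equal(cohens_kappa(round(ind * 3))$kappa, 0, tolerance = 1e-12)

  # invariant under simultaneous row/column permutation
  p <- c(3, 1, 4, 2)
  expect_equal(cohens_kappa(tab[p, p])$kappa, out$kappa, tolerance = 1e-12)

  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  expect_equal(out$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)

  expect_error(cohens_kappa(matrix(1:6, 2, 3)), "square")
  expect_equal(cohens_kappa(matrix(c(4, 0, 0, 0), 2, 2))$kappa, 1)
})

test_that("synthetic cohorts separate the clinical groups reliably", {
  # scaled-down end-to-end power check: t test and ROC on plaque summaries
  hits <- 0L
  n_runs <- 100L
  for (s in seq_len(n_runs)) {
    co <- make_cohort(small_spec(seed = s),   # study-sized: 15 + 11 plaques
                      small_config(), histology_emulation())
    slices <- list()
    for (p in co$plaques) for (sl in p$slices) {
      m <- fit_slice(sl$series, sl$roi)
      cls <- classify_voxels(m, sl$roi, threshold_pair(42, 90))
      slices[[length(slices) + 1L]] <-
        cbind(measure_slice(cls, sl$roi, plaque_id = p$plaque_id),
              symptomatic = p$symptomatic)
    }
    sdf <- do.call(rbind, slices)
    pl <- do.call(rbind, lapply(split(sdf, sdf$plaque_id), function(d)
      data.frame(lipid = mean(d$lipid_area_pct), sym = d$symptomatic[1])))
    tt <- two_sample_t(pl$lipid[pl$sym], pl$lipid[!pl$sym])
    roc <- roc_analysis(pl$lipid, pl$sym)
    if (tt$p < 0.05 && roc$auc > 0.7) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})
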