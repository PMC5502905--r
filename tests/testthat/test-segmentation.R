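test_that("voxel classification follows the strict dual-threshold rule", {
  t2 <- matrix(c(30, 42, 100, 60, 90, 41.999), 2, 3)
  valid <- matrix(TRUE, 2, 3)
  roi <- wall_roi(matrix(FALSE, 2, 3), matrix(TRUE, 2, 3))
  thr <- threshold_pair(42, 90)

  cls <- classify_voxels(list(t2 = t2, valid = valid), roi, thr, "dual")
  expect_identical(cls[1, 1], "lrnc_short")   # 30 ms
  expect_identical(cls[2, 1], "other")        # exactly 42: boundary excluded
  expect_identical(cls[1, 2], "lrnc_iph")     # 100 ms
  expect_identical(cls[2, 2], "other")        # 60 ms
  expect_identical(cls[1, 3], "other")        # exactly 90: boundary excluded
  expect_identical(cls[2, 3], "lrnc_short")   # just below 42

  # single_low mode ignores the upper threshold
  cls1 <- classify_voxels(list(t2 = t2, valid = valid), roi, thr, "single_low")
  expect_identical(cls1[1, 2], "other")

  # invalid fits are excluded from the wall bookkeeping
  valid[1, 1] <- FALSE
  cls2 <- classify_voxels(list(t2 = t2, valid = valid), roi, thr)
  expect_identical(cls2[1, 1], "invalid")
})

test_that("slice measurement arithmetic and the 5% IPH rule are exact", {
  n <- 10  # 100-voxel wall
  roi <- wall_roi(matrix(FALSE, n, n), matrix(TRUE, n, n), voxel_area = 0.04)
  cm <- matrix("other", n, n)
  cm[1:25] <- "lrnc_short"
  ms <- measure_slice(cm, roi)
  expect_equal(ms$lipid_area_pct, 25)
  expect_equal(ms$wall_area_mm2, 100 * 0.04)

  # exactly 5% IPH is not significant (strict >)
  cm5 <- matrix("other", n, n); cm5[1:5] <- "lrnc_iph"
  ms5 <- measure_slice(cm5, roi)
  expect_equal(ms5$iph_area_pct, 5)
  expect_false(ms5$significant_iph)
  cm6 <- cm5; cm6[6] <- "lrnc_iph"
  expect_true(measure_slice(cm6, roi)$significant_iph)

  expect_error(measure_slice(cm, wall_roi(matrix(TRUE, n, n),
                                          matrix(TRUE, n, n))), "empty wall")
})

test_that("measured percentages match a per-voxel counting oracle", {
  set.seed(21)
  for (i in 1:20) {
    x <- random_map_roi(14)
    thr <- threshold_pair(runif(1, 30, 50), runif(1, 70, 120))
    cls <- classify_voxels(x$t2map, x$roi, thr)
    ms <- measure_slice(cls, x$roi)
    # independent brute-force count over wall voxels
    w <- which(x$roi$wall_mask)
    t2w <- x$t2map$t2[w]; vw <- x$t2map$valid[w]
    n_lip <- sum(vw & (t2w < thr$t2l | t2w > thr$t2h))
    n_iph <- sum(vw & t2w > thr$t2h)
    expect_equal(ms$lipid_area_pct, 100 * n_lip / sum(vw))
    expect_equal(ms$iph_area_pct, 100 * n_iph / sum(vw))
    expect_lte(ms$iph_area_pct, ms$lipid_area_pct)
  }
})

test_that("class counts partition the wall and respond monotonely to thresholds", {
  set.seed(33)
  for (i in 1:200) {
    x <- random_map_roi(12)
    thr <- threshold_pair(runif(1, 30, 50), runif(1, 70, 120))
    cls <- classify_voxels(x$t2map, x$roi, thr)
    w <- x$roi$wall_mask
    counts <- table(factor(cls[w], c("lrnc_short", "lrnc_iph", "other",
                                     "invalid")))
    expect_identical(sum(counts), sum(w))

    # dual-mode area is never below single-low area
    ms_d <- measure_slice(cls, x$roi)
    ms_s <- measure_slice(classify_voxels(x$t2map, x$roi, thr, "single_low"),
                          x$roi)
    expect_gte(ms_d$lipid_area_pct, ms_s$lipid_area_pct)

    # lowering t2l or raising t2h never increases the lipid area
    thr_lo <- threshold_pair(thr$t2l - 5, thr$t2h)
    thr_hi <- threshold_pair(thr$t2l, thr$t2h + 5)
    expect_lte(measure_slice(classify_voxels(x$t2map, x$roi, thr_lo),
                             x$roi)$lipid_area_pct, ms_d$lipid_area_pct)
    expect_lte(measure_slice(classify_voxels(x$t2map, x$roi, thr_hi),
                             x$roi)$lipid_area_pct, ms_d$lipid_area_pct)
  }
})

test_that("noiseless synthetic slices measure their constructed fraction", {
  cfg <- small_config(noise_sigma = 0)
  for (frac in c(10, 25, 45)) {
    tm <- make_tissue_map(cfg, frac, 0, seed = frac)
    ser <- simulate_echo_series(tm, cfg, seed = 1)
    roi <- wall_roi_from_tissue(tm)
    m <- fit_slice(ser, roi)
    cls <- classify_voxels(m, roi, threshold_pair(42, 90))
    ms <- measure_slice(cls, roi)
    expect_lte(abs(ms$lipid_area_pct - frac), 100 / tm$n_analyzable)
  }
})

test_that("plaque summaries average slices and accumulate volume", {
  one <- data.frame(plaque_id = 1, slice_index = 1, lipid_area_pct = 20,
                    iph_area_pct = 0, wall_area_mm2 = 50,
                    significant_iph = FALSE, n_wall = 100, n_valid = 100,
                    histology_lipid_pct = NA)
  expect_equal(summarize_plaque(one)$mean_lipid_area_pct, 20)

  two <- rbind(one, transform(one, slice_index = 2, lipid_area_pct = 30,
                              wall_area_mm2 = 60))
  two <- rbind(two, transform(one, slice_index = 3, lipid_area_pct = 10,
                              wall_area_mm2 = 70))
  ps <- summarize_plaque(two, slice_thickness = 2)
  expect_equal(ps$mean_lipid_area_pct, 20)
  expect_equal(ps$volume_mm3, (50 + 60 + 70) * 2)
  expect_identical(ps$n_slices, 3L)

  # area weighting is available but distinct
  expect_equal(summarize_plaque(two, area_weighted = TRUE)$mean_lipid_area_pct,
               (20 * 50 + 30 * 60 + 10 * 70) / 180)

  mixed <- two; mixed$plaque_id[2] <- 2
  expect_error(summarize_plaque(mixed), "mix")
})

test_that("quality filtering keeps scores at or above the cutoff", {
  rec <- data.frame(id = 1:3, quality = c(2, 3, 4))
  kept <- filter_quality(rec)
  expect_identical(kept$id, 2:3)
  expect_identical(attr(kept, "n_excluded"), 1L)

  # a 40-plaque set with 26 scoring >= 3 retains exactly those 26
  set.seed(2)
  q <- sample(c(rep(1:2, 7), rep(3:5, length.out = 26)))
  rec40 <- data.frame(id = seq_along(q), quality = q)
  kept40 <- filter_quality(rec40)
  expect_identical(nrow(kept40), 26L)
  expect_identical(attr(kept40, "n_total"), 40L)

  all5 <- data.frame(quality = rep(5, 6))
  expect_identical(nrow(filter_quality(all5)), 6L)
  expect_error(filter_quality(data.frame(quality = c(0, 3))), "1-5")
})

test_that("polygon contours rasterize by the even-odd voxel-centre rule", {
  # an axis-aligned square from (3.5, 3.5) to (8.5, 8.5) covers centres 4..8
  sq <- cbind(c(3.5, 8.5, 8.5, 3.5), c(3.5, 3.5, 8.5, 8.5))
  mask <- contour_to_mask(sq, 12)
  expect_identical(which(mask, arr.ind = TRUE),
                   which(outer(1:12, 1:12, function(x, y)
                     x >= 4 & x <= 8 & y >= 4 & y <= 8), arr.ind = TRUE))
  expect_error(contour_to_mask(sq[1:2, ], 12), "n >= 3")
})
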