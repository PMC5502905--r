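test_that("tissue map places the requested area fractions", {
  cfg <- small_config()

  # empty core: every wall voxel is fibrous
  tm0 <- make_tissue_map(cfg, 0, 0, seed = 1)
  expect_true(all(tm0$labels[tm0$labels != "background" &
                             tm0$labels != "lumen"] == "wall_fibrous"))

  # requested 25% core achieved within one voxel
  tm <- make_tissue_map(phantom_config(), 25, 0, seed = 2)
  n_core <- sum(tm$labels %in% c("lipid", "iph"))
  expect_lte(abs(n_core / tm$n_analyzable * 100 - 25), 100 / tm$n_analyzable)

  # labels / ground-truth arrays aligned
  expect_identical(dim(tm$labels), dim(tm$true_t2))
  expect_identical(dim(tm$labels), dim(tm$true_s0))
  signal_bearing <- !(tm$labels %in% c("background", "calcium"))
  expect_true(all(tm$true_t2[signal_bearing] > 0))
  expect_true(all(tm$true_t2[tm$labels == "calcium"] == 0))

  # IPH voxels exist and are a strict subset of the core footprint
  tmi <- make_tissue_map(cfg, 20, 10, seed = 3)
  n_iph <- sum(tmi$labels == "iph")
  n_core2 <- sum(tmi$labels %in% c("lipid", "iph"))
  expect_gt(n_iph, 0)
  expect_lt(n_iph, n_core2)
  # the IPH centroid sits deeper inside the core than the core's own rim:
  # its average distance to the core centroid is below the core average
  g <- which(array(tmi$labels %in% c("lipid", "iph"), dim(tmi$labels)),
             arr.ind = TRUE)
  gi <- which(array(tmi$labels == "iph", dim(tmi$labels)), arr.ind = TRUE)
  ctr <- colMeans(g)
  d_core <- mean(sqrt((g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2))
  d_iph <- mean(sqrt((gi[, 1] - ctr[1])^2 + (gi[, 2] - ctr[2])^2))
  expect_lt(d_iph, d_core)
})

test_that("achieved core fraction tracks the request on average and in order", {
  cfg <- small_config()
  fr <- vapply(1:100, function(s) {
    tm <- make_tissue_map(cfg, 30, 0, seed = s)
    unname(tm$achieved_pct["core"])
  }, 0)
  expect_lt(abs(mean(fr) - 30), 0.5)

  achieved <- vapply(c(5, 15, 25, 40, 60), function(f) {
    unname(make_tissue_map(cfg, f, 0, seed = 7)$achieved_pct["core"])
  }, 0)
  expect_true(all(diff(achieved) > 0))
})

test_that("unachievable fractions raise informative errors", {
  cfg <- small_config()
  expect_error(make_tissue_map(cfg, 60, 50, seed = 1), "exceed 100")
  expect_error(make_tissue_map(cfg, 0.05, 0, seed = 1), "resolution")
  expect_error(make_tissue_map(cfg, 0, 0, calcium_fraction = 0.05, seed = 1),
               "resolution")
})

test_that("echo simulation follows the monoexponential forward model", {
  cfg <- phantom_config(image_size = 16, lumen_radius = 3, outer_radius = 6,
                        echo_times = c(10, 50, 90), noise_sigma = 0)
  tm <- make_tissue_map(cfg, 0, 0, seed = 1)
  # force a known voxel value
  idx <- which(tm$labels == "wall_fibrous")[1]
  tm$true_t2[idx] <- 50; tm$true_s0[idx] <- 100
  ser <- simulate_echo_series(tm, cfg, seed = 1)
  expect_equal(ser$data[row(tm$labels)[idx], col(tm$labels)[idx], 2],
               100 * exp(-1), tolerance = 1e-12)
  # TE -> 0 recovers S0
  cfg0 <- cfg; cfg0$echo_times <- c(1e-9, 50, 90)
  ser0 <- simulate_echo_series(tm, cfg0, seed = 1)
  expect_equal(ser0$data[row(tm$labels)[idx], col(tm$labels)[idx], 1],
               100, tolerance = 1e-6)
})

test_that("rician background magnitudes have the Rayleigh mean", {
  cfg <- phantom_config(image_size = 32, lumen_radius = 4, outer_radius = 8,
                        echo_times = c(10, 50, 90), noise_sigma = 5)
  tm <- make_tissue_map(cfg, 0, 0, seed = 1)
  ser <- simulate_echo_series(tm, cfg, seed = 9)
  bg <- ser$data[, , 1][tm$labels == "background"]
  bg <- c(bg, ser$data[, , 2][tm$labels == "background"],
          ser$data[, , 3][tm$labels == "background"])
  expect_gt(length(bg), 2000)
  expect_equal(mean(bg), 5 * sqrt(pi / 2), tolerance = 0.03)
})

test_that("cohort generation is reproducible and hits the group means", {
  spec <- small_spec(seed = 11)
  cfg <- small_config()
  em <- histology_emulation()
  c1 <- make_cohort(spec, cfg, em, simulate_images = FALSE)
  c2 <- make_cohort(spec, cfg, em, simulate_images = FALSE)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$plaques[[3]]$slices[[1]]$tissue$labels,
                   c2$plaques[[3]]$slices[[1]]$tissue$labels)
  expect_identical(c1$plaques[[5]]$slices[[1]]$histology_lipid_pct,
                   c2$plaques[[5]]$slices[[1]]$histology_lipid_pct)

  # noise-off histology equals the generated fraction exactly
  c0 <- make_cohort(small_spec(seed = 3),
                    cfg, histology_emulation(area_jitter_sd = 0, bias = 0),
                    simulate_images = FALSE)
  sl <- c0$plaques[[1]]$slices[[1]]
  expect_identical(sl$histology_lipid_pct, sl$true_core_pct)

  # grand group means over many seeded cohorts approach the targets
  sums <- c(sym = 0, asym = 0, n_sym = 0, n_asym = 0, slices = 0, plaques = 0)
  for (s in 1:200) {
    co <- make_cohort(small_spec(seed = s, n_symptomatic = 4, n_asymptomatic = 3),
                      cfg, histology_emulation(), simulate_images = FALSE)
    tt <- co$table
    sums["sym"] <- sums["sym"] + sum(tt$true_core_mean_pct[tt$symptomatic])
    sums["asym"] <- sums["asym"] + sum(tt$true_core_mean_pct[!tt$symptomatic])
    sums["n_sym"] <- sums["n_sym"] + sum(tt$symptomatic)
    sums["n_asym"] <- sums["n_asym"] + sum(!tt$symptomatic)
    sums["slices"] <- sums["slices"] + sum(tt$n_slices)
    sums["plaques"] <- sums["plaques"] + nrow(tt)
  }
  expect_lt(abs(sums["sym"] / sums["n_sym"] - 31.5), 1)
  expect_lt(abs(sums["asym"] / sums["n_asym"] - 15.8), 1)
  # about 2.3 slices per plaque, i.e. ~60 slices for 26 plaques
  expect_lt(abs(sums["slices"] / sums["plaques"] - 2.3), 0.15)
})

test_that("scan-rescan pairs share truth and differ only by noise and shift", {
  cfg <- small_config(noise_sigma = 0)
  spec <- small_spec(seed = 5, n_symptomatic = 1, n_asymptomatic = 1)
  co <- make_cohort(spec, cfg, histology_emulation())
  pr <- make_rescan_pair(co$plaques[[1]], cfg, seed = 2, max_shift = 0L)
  for (k in seq_along(pr$A))
    expect_identical(pr$A[[k]]$series$data, pr$B[[k]]$series$data)

  # with noise on and no shift, lipid differences are centred at zero
  cfgn <- small_config()
  co2 <- make_cohort(small_spec(seed = 8, n_symptomatic = 3, n_asymptomatic = 2),
                     cfgn, histology_emulation())
  d <- vapply(1:50, function(i) {
    p <- co2$plaques[[(i - 1) %% length(co2$plaques) + 1]]
    pr <- make_rescan_pair(p, cfgn, seed = 100 + i, max_shift = 0L)
    lip <- function(scan) mean(vapply(scan, function(sl) {
      m <- fit_slice(sl$series, sl$roi)
      cm <- classify_voxels(m, sl$roi, threshold_pair(42, 90))
      measure_slice(cm, sl$roi)$lipid_area_pct
    }, 0))
    lip(pr$A) - lip(pr$B)
  }, 0)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.5)
})
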