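# Shared fixtures: scaled-down phantom geometries so simulation-heavy tests
# stay fast, and a builder for fitted calibration slices.

small_config <- function(...) {
  phantom_config(image_size = 32L, lumen_radius = 4, outer_radius = 8, ...)
}

small_spec <- function(...) {
  cohort_spec(outer_radius_sym = 8.3, outer_radius_asym = 7.7,
              outer_radius_sd = 0.4, ...)
}

default_te <- function() seq(9, 127, length.out = 14)

# Fitted calibration slices (t2map + roi + histology) from a synthetic
# cohort; the workhorse input for calibration and pipeline tests.
make_cal_slices <- function(seed = 1, n_sym = 4, n_asym = 3,
                            config = small_config(),
                            emulation = histology_emulation(),
                            spec_args = list()) {
  spec <- do.call(small_spec, c(list(seed = seed, n_symptomatic = n_sym,
                                     n_asymptomatic = n_asym), spec_args))
  co <- make_cohort(spec, config, emulation)
  slices <- list()
  for (p in co$plaques) {
    for (sl in p$slices) {
      m <- fit_slice(sl$series, sl$roi)
      slices[[length(slices) + 1L]] <- list(
        t2map = m, roi = sl$roi,
        histology_lipid_pct = sl$histology_lipid_pct,
        true_core_pct = sl$true_core_pct,
        iph_core_fraction = sl$iph_core_fraction,
        plaque_id = p$plaque_id, slice_index = sl$slice_index)
    }
  }
  slices
}

# Random synthetic T2 map + ROI pair on a small grid, for bookkeeping
# property tests (no fitting involved).
random_map_roi <- function(n = 16) {
  g <- matrix(runif(n * n, 10, 130), n, n)
  valid <- matrix(runif(n * n) > 0.1, n, n)
  ctr <- (n + 1) / 2
  d <- sqrt(outer(seq_len(n), rep(1, n)) * 0 +
            (row(g) - ctr)^2 + (col(g) - ctr)^2)
  outer_m <- d < n / 2 - 1
  lumen_m <- d < n / 6
  roi <- wall_roi(lumen_m, outer_m)
  list(t2map = list(t2 = g, valid = valid), roi = roi)
}
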