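## Synthetic multi-echo carotid phantom: digital vessel cross-sections with a
## lipid-rich necrotic core (optionally containing recent haemorrhage and
## calcification), forward-simulated through the monoexponential decay model
## S(TE) = S0 * exp(-TE / T2) with Rician or Gaussian noise, plus matched
## "histology" ground truth and cohort-level clinical metadata.

#' Phantom configuration for the synthetic multi-echo vessel simulator
#'
#' Defines the geometry, tissue T2/S0 distributions, echo train and noise
#' model used by [make_tissue_map()] and [simulate_echo_series()].
#'
#' Component T2 distributions are truncated normals (mean, sd, lower, upper,
#' all ms). The defaults place lipid entirely below 40 ms, fibrous wall in
#' 44--89 ms and recent intraplaque haemorrhage (IPH) above 93 ms, so the
#' dual segmentation thresholds of 42 and 90 ms separate the components by
#' construction, while each class keeps appreciable density at the gap
#' edges (together with the per-slice class-mean shifts, this makes any
#' threshold outside the gaps pay a correlation penalty, which is what lets
#' the calibration recover the generating pair). Calcium is modelled as a
#' signal void (near-zero proton density), not as a T2 class.
#'
#' @param image_size Voxels per side of the square slice grid.
#' @param slice_thickness Slice thickness in mm.
#' @param echo_times Echo times in ms, strictly increasing.
#' @param lumen_radius,outer_radius Lumen and outer-wall radii in voxels.
#' @param component_t2 Named list of `c(mean, sd, lower, upper)` (ms) for
#'   tissue classes `lipid`, `wall_fibrous`, `iph`, `lumen`.
#' @param component_t2_shift_sd Named numeric vector: standard deviation of
#'   a per-slice random shift of each class mean T2 (ms), emulating
#'   between-patient variation in tissue composition; the absolute
#'   truncation bounds are not shifted.
#' @param component_s0 Named numeric vector of mean proton-density signal per
#'   class (arbitrary units), including `calcium` and `background`.
#' @param noise_sigma Noise standard deviation, signal units.
#' @param noise_model `"rician"` (magnitude of a complex Gaussian
#'   perturbation, the magnitude-MRI default) or `"gaussian"`.
#' @param voxel_area In-plane voxel area, mm^2.
#' @param seed Integer seed recorded in the configuration.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(image_size = 64L,
                           slice_thickness = 2,
                           echo_times = seq(9, 127, length.out = 14),
                           lumen_radius = 8,
                           outer_radius = 16,
                           component_t2 = list(
                             lipid        = c(mean = 34, sd = 5,  lower = 15, upper = 40),
                             wall_fibrous = c(mean = 58, sd = 14, lower = 44, upper = 89),
                             iph          = c(mean = 96, sd = 4,  lower = 93, upper = 130),
                             lumen        = c(mean = 200, sd = 20, lower = 150, upper = 250)
                           ),
                           component_t2_shift_sd = c(lipid = 4, wall_fibrous = 12,
                                                     iph = 6, lumen = 0),
                           component_s0 = c(lipid = 100, wall_fibrous = 100,
                                            iph = 100, lumen = 15,
                                            calcium = 0, background = 0),
                           noise_sigma = 1.5,
                           noise_model = c("rician", "gaussian"),
                           voxel_area = 0.04,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_number(image_size, "image_size", lower = 8)
  check_number(slice_thickness, "slice_thickness", lower = 0)
  if (length(echo_times) < 3L || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0))
    stop2("'echo_times' must be >= 3 strictly increasing positive values (ms)")
  check_number(lumen_radius, "lumen_radius", lower = 1)
  check_number(outer_radius, "outer_radius", lower = lumen_radius + 1)
  if (outer_radius <= lumen_radius) stop2("'outer_radius' must exceed 'lumen_radius'")
  for (cls in c("lipid", "wall_fibrous", "iph", "lumen")) {
    p <- component_t2[[cls]]
    if (is.null(p) || length(p) != 4L || p[1] <= 0 || p[2] < 0 || p[3] >= p[4])
      stop2(sprintf("component_t2$%s must be c(mean > 0, sd >= 0, lower < upper)", cls))
  }
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(voxel_area, "voxel_area", lower = 0)
  structure(list(image_size = as.integer(image_size),
                 slice_thickness = slice_thickness,
                 echo_times = as.numeric(echo_times),
                 lumen_radius = lumen_radius,
                 outer_radius = outer_radius,
                 component_t2 = component_t2,
                 component_t2_shift_sd = component_t2_shift_sd,
                 component_s0 = component_s0,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 voxel_area = voxel_area,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Histology emulation parameters
#'
#' Measurement noise applied to the generated true lipid-core area percentage
#' to emulate manual histology planimetry.
#'
#' @param area_jitter_sd Absolute noise sd on the area percentage. The
#'   default is small enough that threshold calibration against the emulated
#'   histology is stable at the study's cohort size; real histology
#'   planimetry is noisier.
#' @param bias Systematic offset, percentage points.
#' @return An object of class `histology_emulation`.
#' @export
histology_emulation <- function(area_jitter_sd = 2, bias = 0) {
  check_number(area_jitter_sd, "area_jitter_sd", lower = 0)
  check_number(bias, "bias")
  structure(list(area_jitter_sd = area_jitter_sd, bias = bias),
            class = "histology_emulation")
}

#' Cohort specification for synthetic symptomatic/asymptomatic plaques
#'
#' Defaults emulate the validation study conditions: 15 symptomatic and 11
#' asymptomatic plaques, group mean lipid-core areas of 31.5\% and 15.8\% of
#' the wall cross-section, about 2.3 analyzable slices per plaque, and
#' significant haemorrhage in roughly a quarter of slices.
#'
#' @param n_symptomatic,n_asymptomatic Plaque counts per group.
#' @param lipid_fraction_mean_sym,lipid_fraction_mean_asym Target group mean
#'   lipid-core area (\% of wall area).
#' @param lipid_fraction_sd Between-plaque sd of the core fraction (\%).
#' @param within_plaque_sd Slice-to-slice sd around the plaque mean (\%).
#' @param slices_per_plaque Mean slices per plaque; slice counts are drawn as
#'   `1 + Poisson(slices_per_plaque - 1)`.
#' @param iph_slice_probability Probability that a slice carries significant
#'   haemorrhage inside its core.
#' @param outer_radius_sym,outer_radius_asym Mean outer-wall radius (voxels)
#'   per group; the modest group difference in plaque volume follows from it.
#' @param outer_radius_sd Between-plaque sd of the outer radius (voxels).
#' @param calcified_probability Probability that a plaque is substantially
#'   calcified.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_symptomatic = 15L,
                        n_asymptomatic = 11L,
                        lipid_fraction_mean_sym = 31.5,
                        lipid_fraction_mean_asym = 15.8,
                        lipid_fraction_sd = 8,
                        within_plaque_sd = 5,
                        slices_per_plaque = 2.3,
                        iph_slice_probability = 0.27,
                        outer_radius_sym = 16.6,
                        outer_radius_asym = 15.4,
                        outer_radius_sd = 0.8,
                        calcified_probability = 0.25,
                        seed = 1L) {
  check_number(n_symptomatic, "n_symptomatic", lower = 1)
  check_number(n_asymptomatic, "n_asymptomatic", lower = 1)
  check_number(lipid_fraction_mean_sym, "lipid_fraction_mean_sym", 0, 100)
  check_number(lipid_fraction_mean_asym, "lipid_fraction_mean_asym", 0, 100)
  check_number(lipid_fraction_sd, "lipid_fraction_sd", lower = 0)
  check_number(within_plaque_sd, "within_plaque_sd", lower = 0)
  check_number(slices_per_plaque, "slices_per_plaque", lower = 1)
  check_number(iph_slice_probability, "iph_slice_probability", 0, 1)
  check_number(calcified_probability, "calcified_probability", 0, 1)
  structure(list(n_symptomatic = as.integer(n_symptomatic),
                 n_asymptomatic = as.integer(n_asymptomatic),
                 lipid_fraction_mean_sym = lipid_fraction_mean_sym,
                 lipid_fraction_mean_asym = lipid_fraction_mean_asym,
                 lipid_fraction_sd = lipid_fraction_sd,
                 within_plaque_sd = within_plaque_sd,
                 slices_per_plaque = slices_per_plaque,
                 iph_slice_probability = iph_slice_probability,
                 outer_radius_sym = outer_radius_sym,
                 outer_radius_asym = outer_radius_asym,
                 outer_radius_sd = outer_radius_sd,
                 calcified_probability = calcified_probability,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Radial distance of every voxel from the grid centre.
.grid_geometry <- function(image_size) {
  ctr <- (image_size + 1) / 2
  x <- matrix(rep(seq_len(image_size), image_size), image_size)
  y <- t(x)
  list(r = sqrt((x - ctr)^2 + (y - ctr)^2),
       theta = atan2(y - ctr, x - ctr), x = x, y = y)
}

#' Construct a ground-truth tissue map for one vessel cross-section
#'
#' Builds an annular vessel wall between `lumen_radius` and `outer_radius`
#' and places a contiguous lipid-rich core occupying the requested fraction
#' of the wall area, with an optional haemorrhage (IPH) region nested inside
#' the core and an optional calcified sector elsewhere in the wall. Per-voxel
#' true T2 values are drawn from the class-specific truncated normal
#' distributions of the configuration.
#'
#' @param config A [phantom_config()].
#' @param lipid_fraction Lipid-only core area, \% of the analyzable
#'   (non-calcified) wall area -- the same denominator convention the
#'   segmentation measurements use, since signal-void voxels never yield a
#'   valid fit.
#' @param iph_fraction Haemorrhagic core area, \% of analyzable wall area.
#'   The total necrotic core occupies `lipid_fraction + iph_fraction`; the
#'   IPH voxels are spatially interior to the core.
#' @param calcium_fraction Calcified area, \% of total wall area (signal
#'   void).
#' @param seed Integer seed for region placement and the T2 draws.
#' @return An object of class `tissue_map`: matrices `labels` (character:
#'   `background`, `lumen`, `wall_fibrous`, `lipid`, `iph`, `calcium`),
#'   `true_t2` (ms; 0 where no transverse signal exists), `true_s0`, the
#'   logical `calcium_mask`, and the achieved area fractions.
#' @export
make_tissue_map <- function(config, lipid_fraction, iph_fraction = 0,
                            calcium_fraction = 0, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  check_number(lipid_fraction, "lipid_fraction", 0, 100)
  check_number(iph_fraction, "iph_fraction", 0, 100)
  check_number(calcium_fraction, "calcium_fraction", 0, 100)
  if (lipid_fraction + iph_fraction > 100)
    stop2("lipid_fraction + iph_fraction must not exceed 100")
  n <- config$image_size
  g <- .grid_geometry(n)
  labels <- matrix("background", n, n)
  labels[g$r < config$outer_radius] <- "wall_fibrous"
  labels[g$r < config$lumen_radius] <- "lumen"
  wall_idx <- which(labels == "wall_fibrous")
  n_wall <- length(wall_idx)
  if (n_wall == 0L) stop2("geometry yields an empty wall")

  frac_to_count <- function(frac, base, what) {
    k <- round(frac / 100 * base)
    if (frac > 0 && k == 0L)
      stop2(sprintf(
        "%s fraction %.3g%% is below the resolution of this geometry (minimum nonzero %.3g%%, maximum 100%%)",
        what, frac, 100 / base))
    k
  }
  ## Calcium is carved out first; core fractions refer to the analyzable
  ## (non-calcified) wall, matching the measurement convention that signal
  ## voids are excluded from area denominators.
  k_cal  <- frac_to_count(calcium_fraction, n_wall, "calcium")
  n_analyzable <- n_wall - k_cal
  if (n_analyzable < 1L)
    stop2("calcium fraction leaves no analyzable wall")
  k_core <- frac_to_count(lipid_fraction + iph_fraction, n_analyzable, "core")
  k_iph  <- frac_to_count(iph_fraction, n_analyzable, "IPH")
  if (k_core + k_cal > n_wall)
    stop2(sprintf(
      "requested fractions need %d wall voxels but only %d exist; achievable combined maximum at this geometry is %.1f%%",
      k_core + k_cal, n_wall, 100))

  with_seed(seed, {
    ## Core: the angular sector (full wall thickness) nearest a random
    ## direction -- contiguous by construction.
    phi <- stats::runif(1, -pi, pi)
    dtheta <- abs(atan2(sin(g$theta - phi), cos(g$theta - phi)))
    if (k_cal > 0L) {
      ## Calcium: a sector opposite the (future) core direction.
      dtheta_op <- abs(atan2(sin(g$theta - phi - pi), cos(g$theta - phi - pi)))
      labels[wall_idx[order(dtheta_op[wall_idx])][seq_len(k_cal)]] <- "calcium"
    }
    if (k_core > 0L) {
      ## Core: the angular sector (full wall thickness) nearest the core
      ## direction, from the analyzable (non-calcified) wall -- contiguous
      ## by construction.
      avail <- which(labels == "wall_fibrous")
      core_idx <- avail[order(dtheta[avail])][seq_len(k_core)]
      labels[core_idx] <- "lipid"
      if (k_iph > 0L) {
        ## IPH: the innermost core voxels around the core centroid.
        cx <- mean(g$x[core_idx]); cy <- mean(g$y[core_idx])
        d <- sqrt((g$x[core_idx] - cx)^2 + (g$y[core_idx] - cy)^2)
        labels[core_idx[order(d)][seq_len(k_iph)]] <- "iph"
      }
    }

    true_t2 <- matrix(0, n, n)
    true_s0 <- matrix(0, n, n)
    for (cls in c("lipid", "wall_fibrous", "iph", "lumen")) {
      idx <- which(labels == cls)
      if (length(idx)) {
        p <- config$component_t2[[cls]]
        ## per-slice shift of the class mean (between-patient tissue
        ## variation); the absolute class bounds stay put
        sh <- config$component_t2_shift_sd
        shift <- if (!is.null(sh) && !is.na(sh[cls]))
          stats::rnorm(1, 0, sh[[cls]]) else 0
        true_t2[idx] <- rtruncnorm(length(idx), p[1] + shift, p[2], p[3], p[4])
        true_s0[idx] <- config$component_s0[[cls]]
      }
    }
    true_s0[labels == "calcium"] <- config$component_s0[["calcium"]]
    ## Core and IPH percentages are of the analyzable wall; calcium of the
    ## full wall cross-section.
    achieved <- c(core = k_core / n_analyzable * 100,
                  iph = k_iph / n_analyzable * 100,
                  calcium = k_cal / n_wall * 100)
    structure(list(labels = labels, true_t2 = true_t2, true_s0 = true_s0,
                   calcium_mask = labels == "calcium",
                   achieved_pct = achieved, n_wall = n_wall,
                   n_analyzable = n_analyzable,
                   config = config, seed = as.integer(seed)),
              class = "tissue_map")
  })
}

#' Forward-simulate a multi-echo spin-echo series from a tissue map
#'
#' Each echo image is `S0 * exp(-TE / T2)` per voxel; voxels without
#' transverse signal (background, calcium) stay at zero before noise. Rician
#' noise is the magnitude of the complex signal plus bivariate Gaussian
#' noise; Gaussian noise is added directly and floored at zero (magnitude
#' images are non-negative).
#'
#' @param tissue A [make_tissue_map()] result.
#' @param config A [phantom_config()]; defaults to the one inside `tissue`.
#' @param seed Integer seed for the noise draw.
#' @param slice_index Slice label carried through to measurements.
#' @return An `echo_series` object: `data` (array size x size x n_echoes),
#'   `echo_times`, `slice_index`, `voxel_area`, `slice_thickness`.
#' @export
simulate_echo_series <- function(tissue, config = tissue$config,
                                 seed = config$seed, slice_index = 1L) {
  stopifnot(inherits(tissue, "tissue_map"), inherits(config, "phantom_config"))
  te <- config$echo_times
  n <- nrow(tissue$true_t2)
  decay <- function(te1) {
    s <- matrix(0, n, n)
    pos <- tissue$true_t2 > 0
    s[pos] <- tissue$true_s0[pos] * exp(-te1 / tissue$true_t2[pos])
    s
  }
  clean <- vapply(te, decay, matrix(0, n, n))
  data <- with_seed(seed, {
    if (config$noise_sigma == 0) clean
    else if (config$noise_model == "rician") {
      e1 <- array(stats::rnorm(length(clean), 0, config$noise_sigma), dim(clean))
      e2 <- array(stats::rnorm(length(clean), 0, config$noise_sigma), dim(clean))
      sqrt((clean + e1)^2 + e2^2)
    } else {
      pmax(clean + array(stats::rnorm(length(clean), 0, config$noise_sigma),
                         dim(clean)), 0)
    }
  })
  echo_series(data, te, slice_index = slice_index,
              voxel_area = config$voxel_area,
              slice_thickness = config$slice_thickness)
}

#' Multi-echo series container
#'
#' @param data Numeric array, grid x grid x n_echoes, non-negative magnitudes.
#' @param echo_times Echo times in ms, strictly increasing, one per image.
#' @param slice_index Integer slice label.
#' @param voxel_area In-plane voxel area, mm^2.
#' @param slice_thickness Slice thickness, mm.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(data, echo_times, slice_index = 1L,
                        voxel_area = 0.04, slice_thickness = 2) {
  if (length(dim(data)) != 3L) stop2("'data' must be a 3-d array (x, y, echo)")
  if (dim(data)[3] != length(echo_times))
    stop2("third dimension of 'data' must match length(echo_times)")
  if (length(echo_times) < 3L || any(diff(echo_times) <= 0) || any(echo_times <= 0))
    stop2("'echo_times' must be >= 3 strictly increasing positive values")
  if (any(!is.finite(data)) || any(data < 0))
    stop2("'data' must be finite and non-negative (magnitude images)")
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 slice_index = as.integer(slice_index),
                 voxel_area = voxel_area, slice_thickness = slice_thickness),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-echo series: %d x %d grid, %d echoes (%.1f-%.1f ms), slice %d\n",
              d[1], d[2], d[3], min(x$echo_times), max(x$echo_times),
              x$slice_index))
  invisible(x)
}

## One synthetic plaque: tissue maps, echo series and ROI per slice plus the
## matched histology readings.
.make_plaque <- function(id, symptomatic, spec, config, emulation, seed,
                         simulate_images = TRUE) {
  with_seed(seed, {
    base_core <- rtruncnorm(1,
      if (symptomatic) spec$lipid_fraction_mean_sym else spec$lipid_fraction_mean_asym,
      spec$lipid_fraction_sd, 0, 100)
    n_slices <- 1L + stats::rpois(1, max(0, spec$slices_per_plaque - 1))
    outer_r <- max(config$lumen_radius + 2,
                   stats::rnorm(1, if (symptomatic) spec$outer_radius_sym
                                   else spec$outer_radius_asym,
                                spec$outer_radius_sd))
    calcified <- stats::runif(1) < spec$calcified_probability
    calcium_pct <- if (calcified) stats::runif(1, 8, 25) else stats::runif(1, 0, 3)
    ## snap sub-resolution calcification to zero so the tissue-map
    ## constructor does not reject it
    g <- .grid_geometry(config$image_size)
    n_wall_est <- sum(g$r < outer_r & g$r >= config$lumen_radius)
    if (round(calcium_pct / 100 * n_wall_est) < 1) calcium_pct <- 0
    n_an_est <- n_wall_est - round(calcium_pct / 100 * n_wall_est)
    quality <- sample(3:5, 1, prob = c(0.3, 0.4, 0.3))
    stenosis <- min(99, max(50, stats::rnorm(1,
      if (symptomatic) 81.3 else 84.1, 9.5)))
    slice_seeds <- sample.int(.Machine$integer.max - 1L, n_slices)

    pc <- config
    pc$outer_radius <- outer_r
    slices <- vector("list", n_slices)
    for (i in seq_len(n_slices)) {
      core_pct <- min(80, max(1, base_core + stats::rnorm(1, 0, spec$within_plaque_sd)))
      has_iph <- stats::runif(1) < spec$iph_slice_probability
      iph_core_frac <- if (has_iph) stats::runif(1, 0.05, 0.95) else 0
      iph_pct <- core_pct * iph_core_frac
      ## snap sub-resolution haemorrhage to zero
      if (round(iph_pct / 100 * n_an_est) < 1) {
        iph_pct <- 0
        iph_core_frac <- 0
      }
      lipid_pct <- core_pct - iph_pct
      tissue <- make_tissue_map(pc, lipid_pct, iph_pct, calcium_pct,
                                seed = slice_seeds[i])
      roi <- wall_roi_from_tissue(tissue)
      series <- if (simulate_images)
        simulate_echo_series(tissue, pc, seed = slice_seeds[i] %% 1000003L + i,
                             slice_index = i)
      else NULL
      hist_pct <- min(100, max(0, core_pct + emulation$bias +
                                 stats::rnorm(1, 0, emulation$area_jitter_sd)))
      slices[[i]] <- list(slice_index = i, tissue = tissue, series = series,
                          roi = roi, true_core_pct = core_pct,
                          true_iph_pct = iph_pct,
                          iph_core_fraction = iph_core_frac,
                          histology_lipid_pct = hist_pct)
    }
    list(plaque_id = id, symptomatic = symptomatic, quality = quality,
         stenosis_pct = stenosis, calcium_pct = calcium_pct,
         outer_radius = outer_r, config = pc, n_slices = n_slices,
         true_core_mean_pct = mean(vapply(slices, `[[`, 0, "true_core_pct")),
         slices = slices, seed = seed)
  })
}

#' Generate a synthetic two-group plaque cohort
#'
#' Draws symptomatic and asymptomatic plaques with per-slice tissue maps,
#' wall ROIs, noisy multi-echo image stacks and jittered histology lipid
#' percentages, plus a per-plaque clinical metadata table (symptom label,
#' stenosis grade, image-quality score 1--5).
#'
#' @param spec A [cohort_spec()].
#' @param config A [phantom_config()].
#' @param emulation A [histology_emulation()].
#' @param simulate_images If `FALSE`, skip the echo-series forward simulation
#'   (ground truth and histology only); useful for statistics-level work.
#' @return A list with `plaques` (list of plaque datasets) and `table` (a
#'   per-plaque `data.frame`); class `synthetic_cohort`.
#' @export
make_cohort <- function(spec = cohort_spec(), config = phantom_config(),
                        emulation = histology_emulation(),
                        simulate_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "phantom_config"),
            inherits(emulation, "histology_emulation"))
  n_tot <- spec$n_symptomatic + spec$n_asymptomatic
  seeds <- derive_seeds((as.numeric(spec$seed) + as.numeric(config$seed)) %%
                          .Machine$integer.max,
                        paste0("plaque", seq_len(n_tot)))
  sym <- c(rep(TRUE, spec$n_symptomatic), rep(FALSE, spec$n_asymptomatic))
  plaques <- vector("list", n_tot)
  for (i in seq_len(n_tot))
    plaques[[i]] <- .make_plaque(i, sym[i], spec, config, emulation, seeds[i],
                                 simulate_images = simulate_images)
  tab <- do.call(rbind, lapply(plaques, function(p)
    data.frame(plaque_id = p$plaque_id, symptomatic = p$symptomatic,
               quality = p$quality, stenosis_pct = p$stenosis_pct,
               calcium_pct = p$calcium_pct, n_slices = p$n_slices,
               true_core_mean_pct = p$true_core_mean_pct)))
  structure(list(plaques = plaques, table = tab, spec = spec,
                 config = config, emulation = emulation),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic plaque cohort: %d symptomatic + %d asymptomatic plaques, %d slices\n",
              sum(x$table$symptomatic), sum(!x$table$symptomatic),
              sum(x$table$n_slices)))
  invisible(x)
}

## Shift a logical mask by integer voxel offsets, zero-filling the border.
.shift_mask <- function(mask, dx, dy) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  xs <- seq_len(n) - dx; ys <- seq_len(m) - dy
  okx <- xs >= 1 & xs <= n; oky <- ys >= 1 & ys <= m
  out[okx, oky] <- mask[xs[okx], ys[oky]]
  out
}

#' Simulate a scan-rescan replicate pair for one plaque
#'
#' Both scans share the plaque's ground-truth tissue maps; each gets an
#' independent noise realization, and the second scan's ROI is shifted by a
#' small random integer in-plane offset emulating patient repositioning.
#'
#' @param plaque One element of `make_cohort()$plaques`.
#' @param config A [phantom_config()]; defaults to the plaque's own.
#' @param seed Integer seed.
#' @param max_shift Maximum ROI shift in voxels per axis (0 disables).
#' @return A list with `A` and `B`, each a list of per-slice
#'   `list(series, roi, slice_index)`.
#' @export
make_rescan_pair <- function(plaque, config = plaque$config, seed = 1L,
                             max_shift = 1L) {
  seeds <- derive_seeds(seed, c("a", "b", "shift"))
  shift <- with_seed(seeds[["shift"]],
                     sample(seq(-max_shift, max_shift), 2, replace = TRUE))
  one_scan <- function(scan_seed, dx, dy) {
    lapply(plaque$slices, function(sl) {
      series <- simulate_echo_series(sl$tissue, config,
                                     seed = (as.numeric(scan_seed) +
                                               sl$slice_index) %%
                                       .Machine$integer.max,
                                     slice_index = sl$slice_index)
      roi <- sl$roi
      if (dx != 0 || dy != 0) {
        roi$lumen_mask <- .shift_mask(roi$lumen_mask, dx, dy)
        roi$outer_mask <- .shift_mask(roi$outer_mask, dx, dy)
        roi$wall_mask <- roi$outer_mask & !roi$lumen_mask
        if (!is.null(roi$exclude_mask)) {
          roi$exclude_mask <- .shift_mask(roi$exclude_mask, dx, dy)
          roi$wall_mask <- roi$wall_mask & !roi$exclude_mask
        }
      }
      list(series = series, roi = roi, slice_index = sl$slice_index)
    })
  }
  list(A = one_scan(seeds[["a"]], 0L, 0L),
       B = one_scan(seeds[["b"]], shift[1], shift[2]))
}
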