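## End-to-end synthetic study: generate a cohort, filter by image quality,
## fit T2 maps, calibrate the segmentation thresholds against histology,
## segment at the calibrated pair, and compute the full statistics battery
## plus AHA-type agreement and scan-rescan reproducibility. One master seed
## fans out to per-stage sub-seeds (see derive_seeds) so the whole bundle is
## a pure function of configuration and seed.

#' Study configuration
#'
#' Bundles the phantom, cohort, histology-emulation, calibration-grid, fit
#' and rule parameters of a full synthetic study.
#'
#' @param phantom A [phantom_config()].
#' @param cohort A [cohort_spec()].
#' @param emulation A [histology_emulation()].
#' @param grid A [calibration_grid()].
#' @param fit_options A [t2_fit_options()].
#' @param aha An [aha_rules()].
#' @param min_quality Minimum retained image-quality score.
#' @param iph_significance_pct Significant-IPH area rule, \% (strict `>`).
#' @param large_core_cutoff Large-core chi-square cutoff, \% (inclusive).
#' @param n_rescan Number of plaques given a rescan replicate.
#' @return A list of class `study_config`.
#' @export
study_config <- function(phantom = phantom_config(),
                         cohort = cohort_spec(),
                         emulation = histology_emulation(),
                         grid = calibration_grid(),
                         fit_options = t2_fit_options(),
                         aha = aha_rules(),
                         min_quality = 3,
                         iph_significance_pct = 5,
                         large_core_cutoff = 25,
                         n_rescan = 9L) {
  structure(list(phantom = phantom, cohort = cohort, emulation = emulation,
                 grid = grid, fit_options = fit_options, aha = aha,
                 min_quality = min_quality,
                 iph_significance_pct = iph_significance_pct,
                 large_core_cutoff = large_core_cutoff,
                 n_rescan = as.integer(n_rescan)),
            class = "study_config")
}

## Fit every slice of every plaque; returns the calibration-slice list.
.fit_cohort_slices <- function(plaques, fit_options) {
  series_list <- list(); roi_list <- list(); meta <- list()
  for (p in plaques) {
    for (sl in p$slices) {
      series_list[[length(series_list) + 1L]] <- sl$series
      roi_list[[length(roi_list) + 1L]] <- sl$roi
      meta[[length(meta) + 1L]] <- list(p = p, sl = sl)
    }
  }
  maps <- fit_slices(series_list, roi_list, fit_options)
  out <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    p <- meta[[i]]$p; sl <- meta[[i]]$sl
    out[[i]] <- list(
        t2map = maps[[i]], roi = sl$roi,
        histology_lipid_pct = sl$histology_lipid_pct,
        true_core_pct = sl$true_core_pct,
        true_iph_pct = sl$true_iph_pct,
        iph_core_fraction = sl$iph_core_fraction,
        plaque_id = p$plaque_id, slice_index = sl$slice_index,
        symptomatic = p$symptomatic)
  }
  out
}

#' Run the full synthetic T2-mapping study
#'
#' Generates a cohort of synthetic plaques, filters by image quality, fits
#' voxel-wise T2 maps, calibrates the dual segmentation thresholds against
#' emulated histology (grid search with leave-one-out cross-validation),
#' segments every slice at the calibrated pair, and computes slice- and
#' plaque-level agreement, symptomatic-versus-asymptomatic discrimination
#' (t test, relative difference, large-core chi-square, ROC), modified AHA
#' type agreement, and scan-rescan reproducibility (ICC, within-subject
#' CoV).
#'
#' @param config A [study_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional output directory; when given, the result bundle
#'   is persisted as `calibration.json`, `slices.csv`, `plaques.csv`,
#'   `stats.json` and `aha.csv`.
#' @return An object of class `t2_study` with elements `cohort_table`,
#'   `calibration`, `mode_comparison`, `slices`, `plaques`, `stats`, `aha`,
#'   `rescan`, `seed`.
#' @export
run_synthetic_study <- function(config = study_config(), seed = 1L,
                                out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(seed, c("cohort", "rescan"))
  with_stage <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop2(sprintf("stage '%s' failed: %s", stage, conditionMessage(e))))

  ## 1. cohort generation
  spec <- config$cohort
  spec$seed <- seeds[["cohort"]]
  cohort <- with_stage("simulate",
                       make_cohort(spec, config$phantom, config$emulation))

  ## 2. image-quality filter
  kept_tab <- filter_quality(cohort$table, config$min_quality)
  plaques <- cohort$plaques[cohort$table$plaque_id %in% kept_tab$plaque_id]

  ## 3. voxel-wise relaxometry
  cal_slices <- with_stage("fit",
                           .fit_cohort_slices(plaques, config$fit_options))

  ## 4. threshold calibration + single-threshold comparison
  calibration <- with_stage("calibrate",
                            calibrate_thresholds(cal_slices, config$grid,
                                                 "dual"))
  modes <- with_stage("calibrate", compare_modes(cal_slices, config$grid))

  ## 5. segmentation at the calibrated pair
  slices_df <- do.call(rbind, lapply(cal_slices, function(s) {
    cm <- classify_voxels(s$t2map, s$roi, calibration$best_pair, "dual")
    measure_slice(cm, s$roi, config$iph_significance_pct,
                  plaque_id = s$plaque_id, slice_index = s$slice_index,
                  histology_lipid_pct = s$histology_lipid_pct)
  }))
  plaques_df <- do.call(rbind, lapply(split(slices_df, slices_df$plaque_id),
    summarize_plaque, slice_thickness = config$phantom$slice_thickness))
  plaques_df <- merge(plaques_df, kept_tab[, c("plaque_id", "symptomatic",
                                               "quality", "stenosis_pct",
                                               "calcium_pct")],
                      by = "plaque_id", sort = TRUE)
  hist_by_plaque <- tapply(slices_df$histology_lipid_pct, slices_df$plaque_id,
                           mean)
  plaques_df$histology_lipid_pct <-
    as.numeric(hist_by_plaque[as.character(plaques_df$plaque_id)])

  ## 6. statistics battery
  slice_agree <- agreement_report(slices_df$lipid_area_pct,
                                  slices_df$histology_lipid_pct)
  plaque_agree <- agreement_report(plaques_df$mean_lipid_area_pct,
                                   plaques_df$histology_lipid_pct)
  sym <- plaques_df$symptomatic
  tt <- two_sample_t(plaques_df$mean_lipid_area_pct[sym],
                     plaques_df$mean_lipid_area_pct[!sym])
  tt_vol <- two_sample_t(plaques_df$volume_mm3[sym],
                         plaques_df$volume_mm3[!sym])
  roc <- roc_analysis(plaques_df$mean_lipid_area_pct, sym)
  chi <- chi2_large_lrnc(plaques_df, config$large_core_cutoff)
  stats_report <- list(
    slice = slice_agree, plaque = plaque_agree,
    groups = c(tt, list(
      relative_difference_pct = relative_difference(tt$mean_a, tt$mean_b))),
    volume = c(tt_vol, list(
      relative_difference_pct = relative_difference(tt_vol$mean_a,
                                                    tt_vol$mean_b))),
    roc = roc[c("auc", "optimal_cutoff", "sensitivity", "specificity")],
    chi2_large_core = chi[c("chi2", "p", "cutoff")],
    n_slices = nrow(slices_df), n_plaques = nrow(plaques_df))

  ## 7. modified AHA typing: reference from ground truth + histology,
  ##    prediction from the T2-map measurements and the calcium mask
  ref <- character(nrow(plaques_df)); prd <- character(nrow(plaques_df))
  for (i in seq_len(nrow(plaques_df))) {
    pid <- plaques_df$plaque_id[i]
    p <- plaques[[which(vapply(plaques, `[[`, 0, "plaque_id") == pid)]]
    true_iph <- any(vapply(p$slices, `[[`, 0, "true_iph_pct") >
                      config$iph_significance_pct)
    ref[i] <- as.character(classify_plaque_aha(
      min(100, p$true_core_mean_pct), true_iph, p$calcium_pct, config$aha))
    prd[i] <- as.character(classify_plaque_aha(
      min(100, plaques_df$mean_lipid_area_pct[i]),
      plaques_df$any_significant_iph[i], p$calcium_pct, config$aha))
  }
  aha_tab <- agreement_table(prd, ref)
  aha <- list(table = aha_tab, kappa = cohens_kappa(aha_tab),
              reference = ref, predicted = prd)

  ## 8. scan-rescan reproducibility on the first n_rescan retained plaques
  n_rescan <- min(config$n_rescan, length(plaques))
  rescan <- NULL
  if (n_rescan >= 3L) {
    rescan_seeds <- derive_seeds(seeds[["rescan"]],
                                 paste0("p", seq_len(n_rescan)))
    lipA <- numeric(n_rescan); lipB <- numeric(n_rescan)
    for (j in seq_len(n_rescan)) {
      pr <- make_rescan_pair(plaques[[j]], plaques[[j]]$config,
                             seed = rescan_seeds[j])
      mean_lip <- function(scan) {
        mean(vapply(scan, function(sl) {
          m <- fit_slice(sl$series, sl$roi, config$fit_options)
          cm <- classify_voxels(m, sl$roi, calibration$best_pair, "dual")
          measure_slice(cm, sl$roi,
                        config$iph_significance_pct)$lipid_area_pct
        }, 0))
      }
      lipA[j] <- mean_lip(pr$A); lipB[j] <- mean_lip(pr$B)
    }
    icc <- icc_absolute(lipA, lipB)
    rescan <- list(icc = icc$icc, icc_ci_low = icc$ci_low,
                   icc_ci_high = icc$ci_high,
                   cov_pct = cov_within(lipA, lipB),
                   pairs = data.frame(plaque_id = vapply(
                     plaques[seq_len(n_rescan)], `[[`, 0, "plaque_id"),
                     scan_a = lipA, scan_b = lipB))
  }

  result <- structure(list(
    cohort_table = cohort$table, kept_table = kept_tab,
    n_excluded = attr(kept_tab, "n_excluded"),
    calibration = calibration, mode_comparison = modes,
    slices = slices_df, plaques = plaques_df, stats = stats_report,
    aha = aha, rescan = rescan, config = config, seed = as.integer(seed)),
    class = "t2_study")
  if (!is.null(out_dir)) write_study_bundle(result, out_dir)
  result
}

#' Persist a study result bundle to disk
#'
#' Writes `calibration.json`, `slices.csv`, `plaques.csv`, `stats.json` and
#' `aha.csv` into `out_dir`. JSON numbers are written at fixed precision so
#' identical runs give byte-identical files.
#'
#' @param study A [run_synthetic_study()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_study_bundle <- function(study, out_dir) {
  stopifnot(inherits(study, "t2_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- study$calibration
  jsonlite::write_json(list(
    seed = study$seed,
    best_t2l = cal$best_pair$t2l, best_t2h = cal$best_pair$t2h,
    best_r = cal$best_r, rmse_pct = cal$rmse_pct, loocv_r = cal$loocv_r,
    single_low_r = study$mode_comparison$single_low$best_r,
    n_heavy_iph_slices = study$mode_comparison$n_heavy),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = 10)
  utils::write.csv(study$slices, file.path(out_dir, "slices.csv"),
                   row.names = FALSE)
  utils::write.csv(study$plaques, file.path(out_dir, "plaques.csv"),
                   row.names = FALSE)
  st <- study$stats
  st$rescan <- if (is.null(study$rescan)) NULL else
    study$rescan[c("icc", "icc_ci_low", "icc_ci_high", "cov_pct")]
  st$aha_kappa <- study$aha$kappa$kappa
  st$aha_agreement_pct <- study$aha$kappa$agreement_pct
  st$seed <- study$seed
  jsonlite::write_json(st, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = 10)
  utils::write.csv(data.frame(plaque_id = study$plaques$plaque_id,
                              reference = study$aha$reference,
                              predicted = study$aha$predicted),
                   file.path(out_dir, "aha.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.t2_study <- function(x, ...) {
  cal <- x$calibration
  cat("Synthetic carotid T2-mapping study\n")
  cat(sprintf("  %d plaques retained (quality >= %g; %d excluded), %d slices\n",
              nrow(x$plaques), x$config$min_quality, x$n_excluded,
              nrow(x$slices)))
  cat(sprintf("  calibrated thresholds: T2L = %g ms, T2H = %g ms\n",
              cal$best_pair$t2l, cal$best_pair$t2h))
  cat(sprintf("  slice R = %.3f (LOOCV %.3f), RMSE = %.1f%%; plaque R = %.3f\n",
              cal$best_r, cal$loocv_r, cal$rmse_pct, x$stats$plaque$r))
  cat(sprintf("  groups: %.1f%% vs %.1f%% lipid (p = %.3g), AUC = %.2f\n",
              x$stats$groups$mean_a, x$stats$groups$mean_b,
              x$stats$groups$p, x$stats$roc$auc))
  if (!is.null(x$rescan))
    cat(sprintf("  scan-rescan: ICC = %.2f (%.2f-%.2f), CoV = %.1f%%\n",
                x$rescan$icc, x$rescan$icc_ci_low, x$rescan$icc_ci_high,
                x$rescan$cov_pct))
  cat(sprintf("  AHA agreement: %.1f%%, kappa = %.2f\n",
              x$aha$kappa$agreement_pct, x$aha$kappa$kappa))
  invisible(x)
}
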