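## Calibration of the dual T2 thresholds against histology: exhaustive grid
## search maximizing the Pearson correlation of per-slice lipid area with
## histology lipid area, and leave-one-out cross-validation of the selected
## pair. The grid evaluation uses sorted wall T2 values and counting
## (strictly-below / strictly-above), which is algebraically identical to
## running the voxel classifier at every grid pair.

#' Threshold search grid
#'
#' @param t2l_range Lower-threshold range (ms), default 30--50.
#' @param t2h_range Upper-threshold range (ms), default 70--120.
#' @param step Grid step (ms).
#' @return An object of class `calibration_grid` with `t2l` and `t2h`
#'   candidate vectors.
#' @export
calibration_grid <- function(t2l_range = c(30, 50), t2h_range = c(70, 120),
                             step = 1) {
  check_number(step, "step", lower = 1e-9)
  if (length(t2l_range) != 2L || length(t2h_range) != 2L ||
      diff(t2l_range) < 0 || diff(t2h_range) < 0)
    stop2("threshold ranges must be length-2 non-decreasing (min, max)")
  if (max(t2l_range) >= min(t2h_range))
    stop2("t2l_range must lie entirely below t2h_range")
  structure(list(t2l = seq(t2l_range[1], t2l_range[2], by = step),
                 t2h = seq(t2h_range[1], t2h_range[2], by = step),
                 step = step),
            class = "calibration_grid")
}

## Valid wall T2 values of one calibration slice (sorted).
.slice_t2vals <- function(s) {
  v <- s$t2map$t2[s$roi$wall_mask & s$t2map$valid]
  sort(v[is.finite(v)])
}

## Counts below / above via binary search on the sorted values; strict
## inequalities on both sides match the voxel classifier.
.lipid_pct_grid <- function(v, t2l, t2h, mode) {
  n <- length(v)
  if (n == 0L) return(matrix(NA_real_, length(t2l), length(t2h)))
  below <- findInterval(t2l, v, left.open = TRUE)   # #{v < t2l}
  if (mode == "single_low")
    return(matrix(100 * below / n, length(t2l), length(t2h)))
  above <- n - findInterval(t2h, v)                 # #{v > t2h}
  100 * outer(below, above, `+`) / n
}

## Slice x pair lipid matrix plus the pair table.
.lipid_matrix <- function(slices, grid, mode) {
  pairs <- expand.grid(t2l = grid$t2l, t2h = grid$t2h,
                       KEEP.OUT.ATTRS = FALSE)
  L <- do.call(rbind, lapply(slices, function(s) {
    as.vector(.lipid_pct_grid(.slice_t2vals(s), grid$t2l, grid$t2h, mode))
  }))
  list(L = L, pairs = pairs)
}

## Pearson r of each column of L with h, plus per-column RMSE.
.column_scores <- function(L, h) {
  n <- length(h)
  hc <- h - mean(h)
  Lc <- sweep(L, 2, colMeans(L))
  sxy <- as.vector(crossprod(Lc, hc))
  sxx <- colSums(Lc^2)
  syy <- sum(hc^2)
  r <- sxy / sqrt(sxx * syy)
  r[sxx <= 0] <- NA_real_
  rmse <- sqrt(colMeans((L - matrix(h, n, ncol(L)))^2))
  list(r = r, rmse = rmse)
}

.check_slices <- function(slices, min_n) {
  if (length(slices) < min_n)
    stop2(sprintf("at least %d slices with histology are required", min_n))
  h <- vapply(slices, function(s) s$histology_lipid_pct, 0)
  if (any(!is.finite(h))) stop2("all slices need finite histology values")
  if (stats::sd(h) == 0)
    stop2("degenerate input: histology values have zero variance")
  h
}

## Deterministic argmax with the tie-break chain: highest r, then lowest
## RMSE, then lowest t2l, then lowest t2h.
.best_index <- function(r, rmse, pairs) {
  ok <- which(is.finite(r))
  if (!length(ok))
    stop2("degenerate input: measured lipid values have zero variance at every threshold pair")
  ok[order(-r[ok], rmse[ok], pairs$t2l[ok], pairs$t2h[ok])[1]]
}

#' Exhaustive threshold grid search against histology
#'
#' For every candidate `(t2l, t2h)` pair, computes the per-slice lipid area
#' percentage that the dual-threshold classifier would produce and its
#' Pearson correlation with the histology lipid percentages; returns the
#' pair with the highest correlation (ties broken by lower RMSE, then lower
#' `t2l`, then lower `t2h`).
#'
#' @param slices List of calibration slices; each element is a list with
#'   `t2map` (a [fit_slice()] result), `roi` (a [wall_roi()]) and
#'   `histology_lipid_pct`, optionally `plaque_id`, `slice_index` and
#'   `iph_core_fraction`.
#' @param grid A [calibration_grid()].
#' @param mode `"dual"` or `"single_low"` (the latter ignores `t2h`).
#' @return An object of class `t2cal`: `best_pair` ([threshold_pair()]),
#'   `best_r`, `rmse_pct` (at the best pair), `grid_scores` (data.frame
#'   `t2l`, `t2h`, `r`, `rmse`), `measured` (per-slice lipid \% at the best
#'   pair), `histology`, `mode`, `n_slices`.
#' @export
grid_search <- function(slices, grid = calibration_grid(),
                        mode = c("dual", "single_low")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "calibration_grid"))
  h <- .check_slices(slices, 3L)
  lm <- .lipid_matrix(slices, grid, mode)
  sc <- .column_scores(lm$L, h)
  best <- .best_index(sc$r, sc$rmse, lm$pairs)
  structure(list(best_pair = threshold_pair(lm$pairs$t2l[best],
                                            lm$pairs$t2h[best]),
                 best_r = sc$r[best], rmse_pct = sc$rmse[best],
                 grid_scores = data.frame(lm$pairs, r = sc$r, rmse = sc$rmse),
                 measured = lm$L[, best], histology = h,
                 mode = mode, grid = grid, n_slices = length(slices)),
            class = "t2cal")
}

#' Leave-one-out cross-validation of the threshold calibration
#'
#' Each slice in turn is held out; the grid search runs on the remaining
#' slices and the winning pair is applied to the held-out slice. The
#' cross-validated Pearson R between held-out predictions and histology
#' estimates out-of-sample segmentation performance.
#'
#' @inheritParams grid_search
#' @return A list: `loocv_r`, `predictions` (held-out lipid \%),
#'   `histology`, `winners` (data.frame of per-fold selected pairs).
#' @export
loocv <- function(slices, grid = calibration_grid(),
                  mode = c("dual", "single_low")) {
  mode <- match.arg(mode)
  h <- .check_slices(slices, 4L)
  lm <- .lipid_matrix(slices, grid, mode)
  n <- length(slices)
  pred <- numeric(n)
  winners <- data.frame(t2l = numeric(n), t2h = numeric(n))
  for (i in seq_len(n)) {
    hi <- h[-i]
    if (stats::sd(hi) == 0)
      stop2("degenerate input: histology values have zero variance in a leave-one-out fold")
    sc <- .column_scores(lm$L[-i, , drop = FALSE], hi)
    best <- .best_index(sc$r, sc$rmse, lm$pairs)
    pred[i] <- lm$L[i, best]
    winners$t2l[i] <- lm$pairs$t2l[best]
    winners$t2h[i] <- lm$pairs$t2h[best]
  }
  if (stats::sd(pred) == 0)
    stop2("degenerate input: held-out measured values have zero variance")
  list(loocv_r = stats::cor(pred, h), predictions = pred, histology = h,
       winners = winners)
}

#' Calibrate thresholds with in-sample and cross-validated performance
#'
#' Convenience wrapper running [grid_search()] and [loocv()] on the same
#' slices; both the in-sample maximum correlation and the leave-one-out
#' estimate are first-class outputs.
#'
#' @inheritParams grid_search
#' @return A `t2cal` object with `loocv_r`, `loocv_predictions` and
#'   `loocv_winners` filled in.
#' @export
calibrate_thresholds <- function(slices, grid = calibration_grid(),
                                 mode = c("dual", "single_low")) {
  mode <- match.arg(mode)
  fit <- grid_search(slices, grid, mode)
  cv <- loocv(slices, grid, mode)
  fit$loocv_r <- cv$loocv_r
  fit$loocv_predictions <- cv$predictions
  fit$loocv_winners <- cv$winners
  fit
}

#' Compare dual-threshold and single-threshold segmentation
#'
#' Reruns the calibration with the upper threshold disabled (so high-T2
#' haemorrhage is not counted as core) and, additionally, after excluding
#' slices whose haemorrhage infiltrates more than `heavy_iph_fraction` of
#' the core.
#'
#' @inheritParams grid_search
#' @param heavy_iph_fraction Core-infiltration fraction above which a slice
#'   counts as heavy-IPH (default 0.5).
#' @return A list of `t2cal` objects `dual`, `single_low`,
#'   `single_low_no_heavy` (and `dual_no_heavy`), plus `n_heavy` and the
#'   subset definition.
#' @export
compare_modes <- function(slices, grid = calibration_grid(),
                          heavy_iph_fraction = 0.5) {
  frac <- vapply(slices, function(s) {
    f <- s$iph_core_fraction
    if (is.null(f) || !is.finite(f)) 0 else f
  }, 0)
  heavy <- frac > heavy_iph_fraction
  keep <- slices[!heavy]
  out <- list(dual = grid_search(slices, grid, "dual"),
              single_low = grid_search(slices, grid, "single_low"),
              n_heavy = sum(heavy),
              subset_definition = sprintf(
                "slices with IPH infiltrating > %.0f%% of the lipid core excluded",
                100 * heavy_iph_fraction))
  if (length(keep) >= 3L && any(heavy)) {
    out$single_low_no_heavy <- grid_search(keep, grid, "single_low")
    out$dual_no_heavy <- grid_search(keep, grid, "dual")
  }
  out
}

#' @export
print.t2cal <- function(x, ...) {
  cat(sprintf("T2 threshold calibration (%s mode, %d slices)\n",
              x$mode, x$n_slices))
  if (x$mode == "dual")
    cat(sprintf("  best pair: T2L = %g ms, T2H = %g ms\n",
                x$best_pair$t2l, x$best_pair$t2h))
  else
    cat(sprintf("  best lower threshold: T2L = %g ms (upper ignored)\n",
                x$best_pair$t2l))
  cat(sprintf("  in-sample R = %.3f, RMSE = %.1f%%\n", x$best_r, x$rmse_pct))
  if (!is.null(x$loocv_r))
    cat(sprintf("  leave-one-out R = %.3f\n", x$loocv_r))
  invisible(x)
}

#' @export
summary.t2cal <- function(object, ...) {
  gs <- object$grid_scores
  top <- gs[order(-gs$r, gs$rmse, gs$t2l, gs$t2h)[seq_len(min(5, nrow(gs)))], ]
  out <- list(cal = object, top = top)
  class(out) <- "summary.t2cal"
  out
}

#' @export
print.summary.t2cal <- function(x, ...) {
  print(x$cal)
  cat("  top grid pairs:\n")
  print(format(x$top, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Apply calibrated thresholds to new slices
#'
#' @param object A `t2cal`.
#' @param newdata List of slices as in [grid_search()] (histology optional).
#' @param ... Unused.
#' @return Numeric vector of per-slice lipid area percentages at the
#'   calibrated thresholds.
#' @export
predict.t2cal <- function(object, newdata, ...) {
  vapply(newdata, function(s) {
    v <- .slice_t2vals(s)
    if (!length(v)) return(NA_real_)
    .lipid_pct_grid(v, object$best_pair$t2l, object$best_pair$t2h,
                    object$mode)[1, 1]
  }, 0)
}

#' Plot the calibration correlation surface
#'
#' @param x A `t2cal` (dual mode).
#' @param ... Passed to [graphics::image()].
#' @export
plot.t2cal <- function(x, ...) {
  gs <- x$grid_scores
  t2l <- sort(unique(gs$t2l)); t2h <- sort(unique(gs$t2h))
  z <- matrix(gs$r[order(gs$t2h, gs$t2l)], length(t2l), length(t2h))
  graphics::image(t2l, t2h, z, xlab = "T2L (ms)", ylab = "T2H (ms)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "Pearson R vs histology", ...)
  graphics::points(x$best_pair$t2l, x$best_pair$t2h, pch = 4, cex = 2,
                   col = "red")
  invisible(x)
}
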