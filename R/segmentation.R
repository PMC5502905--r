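## Dual-threshold lipid-rich-necrotic-core segmentation of vessel-wall T2
## maps and the per-slice / per-plaque area bookkeeping built on it.

#' Vessel-wall region of interest
#'
#' @param lumen_mask,outer_mask Logical matrices; the lumen must lie inside
#'   the outer boundary. The analyzable wall is `outer & !lumen`, minus any
#'   exclusion mask.
#' @param voxel_area In-plane voxel area, mm^2.
#' @param exclude_mask Optional logical matrix of wall voxels to remove from
#'   the analyzable wall — typically the calcium mask identified on the
#'   companion bright-blood (TOF) acquisition, whose signal voids cannot
#'   yield meaningful T2 fits.
#' @return An object of class `wall_roi` with the derived `wall_mask`.
#' @export
wall_roi <- function(lumen_mask, outer_mask, voxel_area = 0.04,
                     exclude_mask = NULL) {
  lumen_mask <- as.matrix(lumen_mask) > 0
  outer_mask <- as.matrix(outer_mask) > 0
  if (!all(dim(lumen_mask) == dim(outer_mask)))
    stop2("lumen and outer masks must share one shape")
  if (any(lumen_mask & !outer_mask))
    stop2("lumen mask must be contained in the outer mask")
  wall <- outer_mask & !lumen_mask
  if (!is.null(exclude_mask)) {
    exclude_mask <- as.matrix(exclude_mask) > 0
    if (!all(dim(exclude_mask) == dim(outer_mask)))
      stop2("exclusion mask must share the grid shape")
    wall <- wall & !exclude_mask
  }
  structure(list(lumen_mask = lumen_mask, outer_mask = outer_mask,
                 wall_mask = wall, exclude_mask = exclude_mask,
                 voxel_area = voxel_area),
            class = "wall_roi")
}

#' @rdname wall_roi
#' @param tissue A [make_tissue_map()] result; masks are taken from its
#'   labels and the calcium mask becomes the exclusion mask.
#' @export
wall_roi_from_tissue <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_map"))
  lumen <- tissue$labels == "lumen"
  lab <- tissue$labels
  dim(lab) <- dim(tissue$labels)
  outer <- lumen | array(lab %in% c("wall_fibrous", "lipid", "iph", "calcium"),
                         dim(lab))
  wall_roi(lumen, outer, voxel_area = tissue$config$voxel_area,
           exclude_mask = tissue$calcium_mask)
}

#' Rasterize a closed polygon contour to a voxel mask
#'
#' A voxel belongs to the mask when its centre is inside the polygon under
#' the even-odd rule (ray casting); this is the documented convention for
#' CSV contour inputs.
#'
#' @param vertices Two-column matrix of (x, y) vertex coordinates in voxel
#'   units (1-based grid coordinates).
#' @param image_size Grid side length.
#' @return Logical `image_size` x `image_size` matrix.
#' @export
contour_to_mask <- function(vertices, image_size) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop2("'vertices' must be an n x 2 matrix with n >= 3")
  vx <- vertices[, 1]; vy <- vertices[, 2]
  nv <- length(vx)
  jj <- c(nv, seq_len(nv - 1L))
  mask <- matrix(FALSE, image_size, image_size)
  for (ix in seq_len(image_size)) {
    px <- ix
    for (iy in seq_len(image_size)) {
      py <- iy
      crosses <- (vy > py) != (vy[jj] > py)
      if (!any(crosses)) next
      xint <- vx[crosses] + (py - vy[crosses]) *
        (vx[jj][crosses] - vx[crosses]) / (vy[jj][crosses] - vy[crosses])
      mask[ix, iy] <- sum(xint > px) %% 2L == 1L
    }
  }
  mask
}

#' Dual T2 segmentation thresholds
#'
#' @param t2l Lower threshold (ms): the maximum T2 associated with lipid
#'   alone; wall voxels strictly below it are lipid core.
#' @param t2h Upper threshold (ms): wall voxels strictly above it are
#'   haemorrhagic core (recent IPH).
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(t2l = 42, t2h = 90) {
  check_number(t2l, "t2l", lower = 0)
  check_number(t2h, "t2h", lower = 0)
  if (t2l >= t2h) stop2("'t2l' must be strictly below 't2h'")
  structure(list(t2l = t2l, t2h = t2h), class = "threshold_pair")
}

#' Classify wall voxels from a T2 map
#'
#' Dual-threshold rule: a valid wall voxel is `lrnc_short` when its T2 lies
#' strictly below `t2l`, `lrnc_iph` when strictly above `t2h`, `other`
#' otherwise (boundary values are non-core); invalid fits are `invalid` and
#' excluded from area denominators. In `single_low` mode the upper threshold
#' is ignored, so high-T2 haemorrhage is not counted as core.
#'
#' @param t2map A [fit_slice()] result (or any list with `t2` and `valid`
#'   matrices).
#' @param roi A [wall_roi()].
#' @param thresholds A [threshold_pair()].
#' @param mode `"dual"` or `"single_low"`.
#' @return Character matrix over the grid with values `lrnc_short`,
#'   `lrnc_iph`, `other`, `invalid`, `outside`.
#' @export
classify_voxels <- function(t2map, roi, thresholds = threshold_pair(),
                            mode = c("dual", "single_low")) {
  mode <- match.arg(mode)
  stopifnot(inherits(roi, "wall_roi"))
  if (!all(dim(t2map$t2) == dim(roi$wall_mask)))
    stop2("T2 map and ROI shapes differ")
  cls <- matrix("outside", nrow(roi$wall_mask), ncol(roi$wall_mask))
  w <- roi$wall_mask
  cls[w] <- "invalid"
  ok <- w & t2map$valid & is.finite(t2map$t2)
  cls[ok] <- "other"
  cls[ok & t2map$t2 < thresholds$t2l] <- "lrnc_short"
  if (mode == "dual") cls[ok & t2map$t2 > thresholds$t2h] <- "lrnc_iph"
  cls
}

#' Per-slice plaque measurements from a class map
#'
#' Area percentages use the valid wall voxels as denominator (invalid fits
#' are excluded from numerator and denominator by default). Significant
#' haemorrhage is a strictly greater-than rule on the IPH area percentage.
#'
#' @param class_map Output of [classify_voxels()].
#' @param roi The matching [wall_roi()].
#' @param iph_significance_pct Threshold (\%) above which IPH is significant.
#' @param plaque_id,slice_index Identifiers carried into the result.
#' @param histology_lipid_pct Optional paired histology lipid area (\%).
#' @param count_invalid_in_denominator If `TRUE`, invalid-fit voxels stay in
#'   the wall denominator.
#' @return A one-row `data.frame`: `plaque_id`, `slice_index`,
#'   `lipid_area_pct`, `iph_area_pct`, `wall_area_mm2`, `significant_iph`,
#'   `n_wall`, `n_valid`, `histology_lipid_pct`.
#' @export
measure_slice <- function(class_map, roi, iph_significance_pct = 5,
                          plaque_id = NA_integer_, slice_index = NA_integer_,
                          histology_lipid_pct = NA_real_,
                          count_invalid_in_denominator = FALSE) {
  stopifnot(inherits(roi, "wall_roi"))
  w <- roi$wall_mask
  if (!any(w)) stop2("empty wall: ROI has no wall voxels")
  cm <- class_map[w]
  n_wall <- length(cm)
  n_valid <- sum(cm != "invalid")
  denom <- if (count_invalid_in_denominator) n_wall else n_valid
  if (denom == 0L) {
    lipid <- NA_real_; iph <- NA_real_
  } else {
    iph <- 100 * sum(cm == "lrnc_iph") / denom
    lipid <- 100 * sum(cm %in% c("lrnc_short", "lrnc_iph")) / denom
  }
  data.frame(plaque_id = plaque_id, slice_index = slice_index,
             lipid_area_pct = lipid, iph_area_pct = iph,
             wall_area_mm2 = n_wall * roi$voxel_area,
             significant_iph = isTRUE(iph > iph_significance_pct),
             n_wall = n_wall, n_valid = n_valid,
             histology_lipid_pct = histology_lipid_pct)
}

#' Summarize a plaque over its slices
#'
#' The plaque lipid burden is the unweighted mean of the slice percentages
#' (an area-weighted mean is available); plaque volume is the summed wall
#' area times slice thickness.
#'
#' @param slices `data.frame` of [measure_slice()] rows for one plaque.
#' @param slice_thickness Slice thickness, mm.
#' @param area_weighted If `TRUE`, weight slice percentages by wall area.
#' @return One-row `data.frame`: `plaque_id`, `mean_lipid_area_pct`,
#'   `mean_iph_area_pct`, `volume_mm3`, `n_slices`, `any_significant_iph`.
#' @export
summarize_plaque <- function(slices, slice_thickness = 2,
                             area_weighted = FALSE) {
  if (nrow(slices) < 1L) stop2("at least one slice is required")
  if (length(unique(slices$plaque_id)) != 1L)
    stop2("slices mix plaque_ids; summarize one plaque at a time")
  wts <- if (area_weighted) slices$wall_area_mm2 else rep(1, nrow(slices))
  data.frame(plaque_id = slices$plaque_id[1],
             mean_lipid_area_pct = stats::weighted.mean(slices$lipid_area_pct, wts),
             mean_iph_area_pct = stats::weighted.mean(slices$iph_area_pct, wts),
             volume_mm3 = sum(slices$wall_area_mm2) * slice_thickness,
             n_slices = nrow(slices),
             any_significant_iph = any(slices$significant_iph))
}

#' Filter records by image-quality score
#'
#' Keeps records whose overall quality score (1 poor -- 5 excellent) is at
#' least `min_quality`; scans below it are excluded from analysis.
#'
#' @param records `data.frame` with a `quality` column of scores in 1--5.
#' @param min_quality Minimum retained score.
#' @return The retained rows, with attributes `n_excluded` and `n_total`.
#' @export
filter_quality <- function(records, min_quality = 3) {
  if (!"quality" %in% names(records)) stop2("'records' needs a 'quality' column")
  q <- records$quality
  if (any(!is.finite(q)) || any(q < 1 | q > 5))
    stop2("quality scores must lie in 1-5")
  keep <- q >= min_quality
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "n_total") <- length(keep)
  out
}
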