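## Voxel-wise T2 relaxometry: nonlinear least-squares fit of the
## monoexponential decay S(TE) = S0 * exp(-TE / T2) to multi-echo magnitude
## data. All wall voxels of a slice are fitted simultaneously by a
## Levenberg-Marquardt iteration vectorized over voxels (the model has only
## two parameters per voxel, so the damped normal equations solve in closed
## form), initialized from the log-linear least-squares solution.

#' Fitting options for the monoexponential T2 fit
#'
#' @param t2_min,t2_max T2 bounds in ms. Fits pinned at a bound are flagged
#'   invalid rather than discarded, so downstream segmentation decides their
#'   fate.
#' @param tol Convergence tolerance on the relative change of the residual
#'   sum of squares.
#' @param max_iter Maximum iterations.
#' @param offset If `TRUE`, add a constant noise-floor offset as a third
#'   parameter (off by default; the decay is modelled as purely
#'   monoexponential).
#' @param min_rsq Optional fit-quality floor in `[0, 1]`; voxels below it are
#'   flagged invalid (`NULL`, the default, disables the floor).
#' @return A list of class `t2_fit_options`.
#' @export
t2_fit_options <- function(t2_min = 1, t2_max = 1000, tol = 1e-8,
                           max_iter = 200L, offset = FALSE, min_rsq = NULL) {
  check_number(t2_min, "t2_min", lower = 0)
  check_number(t2_max, "t2_max", lower = t2_min)
  check_number(tol, "tol", lower = 0)
  check_number(max_iter, "max_iter", lower = 1)
  check_flag(offset, "offset")
  if (!is.null(min_rsq)) check_number(min_rsq, "min_rsq", 0, 1)
  structure(list(t2_min = t2_min, t2_max = t2_max, tol = tol,
                 max_iter = as.integer(max_iter), offset = offset,
                 min_rsq = min_rsq),
            class = "t2_fit_options")
}

## Log-linear initialization: weighted least squares of log(S) on TE using
## only positive samples. Returns s0, t2 (NA where fewer than 2 usable
## echoes). Y is n_voxels x n_echoes.
.loglin_init <- function(Y, te) {
  pos <- Y > 0
  n_pos <- rowSums(pos)
  logY <- suppressWarnings(log(Y))
  logY[!pos] <- 0
  te_m <- matrix(te, nrow(Y), length(te), byrow = TRUE)
  sx <- rowSums(te_m * pos); sy <- rowSums(logY * pos)
  sxx <- rowSums(te_m^2 * pos); sxy <- rowSums(te_m * logY * pos)
  denom <- n_pos * sxx - sx^2
  slope <- (n_pos * sxy - sx * sy) / denom
  inter <- (sy - slope * sx) / n_pos
  t2 <- -1 / slope
  t2[!is.finite(t2) | t2 <= 0] <- NA_real_
  t2[n_pos < 2] <- NA_real_
  list(s0 = exp(inter), t2 = t2)
}

## Vectorized Levenberg-Marquardt for S0*exp(-TE*r) with r = 1/T2, all
## voxels at once. Y: n_voxels x n_echoes. Returns s0, t2, sse, converged.
.fit_monoexp_batch <- function(Y, te, opts) {
  nv <- nrow(Y); ne <- length(te)
  init <- .loglin_init(Y, te)
  s0 <- init$s0
  t2 <- pmin(pmax(init$t2, opts$t2_min), opts$t2_max)
  bad_init <- !is.finite(s0) | !is.finite(t2) | s0 <= 0
  s0[bad_init] <- pmax(Y[, 1][bad_init], .Machine$double.eps)
  t2[bad_init] <- stats::median(te)
  r <- 1 / t2

  sse_full <- function(s0, r, Ysub, tesub) {
    E <- exp(-outer(r, tesub))
    rowSums((s0 * E - Ysub)^2)
  }
  sse <- sse_full(s0, r, Y, te)
  lambda <- rep(1e-3, nv)
  converged <- rep(FALSE, nv)
  active <- seq_len(nv)

  for (it in seq_len(opts$max_iter)) {
    if (!length(active)) break
    ## work only on the still-active voxels
    Ya <- Y[active, , drop = FALSE]
    s0a <- s0[active]; ra <- r[active]; la <- lambda[active]
    ssea <- sse[active]
    E <- exp(-outer(ra, te))
    M <- s0a * E           # model
    res <- Ya - M          # residuals
    ## Jacobian columns: d/ds0 = E, d/dr = -s0 * te * E
    J2 <- -M * rep(te, each = length(active))
    dim(J2) <- dim(M)
    a <- rowSums(E * E); b <- rowSums(E * J2); c <- rowSums(J2 * J2)
    g1 <- rowSums(E * res); g2 <- rowSums(J2 * res)
    ad <- a * (1 + la); cd <- c * (1 + la)
    det <- ad * cd - b * b
    det[det == 0] <- .Machine$double.eps
    ds0 <- (cd * g1 - b * g2) / det
    dr <- (ad * g2 - b * g1) / det

    s0_new <- pmax(s0a + ds0, 0)
    r_new <- pmin(pmax(ra + dr, 1 / opts$t2_max), 1 / opts$t2_min)
    sse_new <- sse_full(s0_new, r_new, Ya, te)

    better <- sse_new <= ssea
    rel <- abs(ssea - sse_new) / pmax(ssea, .Machine$double.eps)
    ib <- active[better]
    s0[ib] <- s0_new[better]
    r[ib] <- r_new[better]
    sse[ib] <- sse_new[better]
    lambda[ib] <- pmax(lambda[ib] / 4, 1e-12)
    iw <- active[!better]
    lambda[iw] <- pmin(lambda[iw] * 8, 1e8)
    done <- better & rel < opts$tol
    converged[active[done]] <- TRUE
    ## voxels whose damping exploded cannot improve further
    stuck <- lambda[active] >= 1e8
    converged[active[stuck & !done]] <- TRUE
    active <- active[!(done | stuck)]
  }
  list(s0 = s0, t2 = 1 / r, sse = sse, converged = converged)
}

#' Fit the monoexponential decay for a single voxel
#'
#' Nonlinear least squares of `S0 * exp(-TE / T2)` on untransformed
#' magnitudes, initialized from the log-linear solution.
#'
#' @param signal Per-echo signal values.
#' @param echo_times Echo times, ms.
#' @param options A [t2_fit_options()].
#' @return A list: `t2` (ms), `s0`, `rsq`, `valid`, `reason` (`"ok"`,
#'   `"no_signal"`, `"at_bound"`, `"not_converged"`, `"low_rsq"`).
#' @examples
#' te <- seq(9, 127, length.out = 14)
#' fit_voxel(100 * exp(-te / 50), te)[c("t2", "s0")]
#' @export
fit_voxel <- function(signal, echo_times, options = t2_fit_options()) {
  if (length(signal) != length(echo_times))
    stop2("'signal' and 'echo_times' must have equal length")
  if (length(signal) < 3L) stop2("at least 3 echoes are required")
  o <- order(echo_times)
  res <- .fit_one_batch(matrix(signal[o], 1), echo_times[o], options)
  lapply(res, `[`, 1)
}

## Shared single-call path used by fit_voxel and fit_slice.
.fit_one_batch <- function(Y, te, opts) {
  nv <- nrow(Y)
  t2 <- rep(NA_real_, nv); s0 <- rep(NA_real_, nv)
  rsq <- rep(NA_real_, nv); valid <- rep(FALSE, nv)
  reason <- rep("no_signal", nv)

  usable <- rowSums(!is.finite(Y)) == 0L & rowSums(Y > 0) > 0L
  if (any(usable)) {
    Yu <- Y[usable, , drop = FALSE]
    if (isTRUE(opts$offset)) fit <- .fit_offset_batch(Yu, te, opts)
    else fit <- .fit_monoexp_batch(Yu, te, opts)
    sst <- rowSums((Yu - rowMeans(Yu))^2)
    r2 <- 1 - fit$sse / pmax(sst, .Machine$double.eps)
    r2 <- pmin(pmax(r2, 0), 1)
    at_bound <- fit$t2 <= opts$t2_min * (1 + 1e-9) |
      fit$t2 >= opts$t2_max * (1 - 1e-9)
    ok <- fit$converged & !at_bound
    rs <- rep("ok", nrow(Yu))
    rs[!fit$converged] <- "not_converged"
    rs[at_bound] <- "at_bound"
    if (!is.null(opts$min_rsq)) {
      low <- ok & r2 < opts$min_rsq
      ok[low] <- FALSE
      rs[low] <- "low_rsq"
    }
    t2[usable] <- fit$t2; s0[usable] <- fit$s0
    rsq[usable] <- r2; valid[usable] <- ok; reason[usable] <- rs
  }
  list(t2 = t2, s0 = s0, rsq = rsq, valid = valid, reason = reason)
}

## Three-parameter variant S0*exp(-TE/T2) + C, fitted per voxel with optim;
## exposed for sensitivity analyses, not the default path.
.fit_offset_batch <- function(Y, te, opts) {
  nv <- nrow(Y)
  base <- .fit_monoexp_batch(Y, te, opts)
  s0 <- base$s0; t2 <- base$t2; sse <- base$sse
  conv <- rep(TRUE, nv)
  for (i in seq_len(nv)) {
    y <- Y[i, ]
    f <- function(p) sum((p[1] * exp(-te / p[2]) + p[3] - y)^2)
    o <- stats::optim(c(base$s0[i], base$t2[i], 0), f, method = "L-BFGS-B",
                      lower = c(0, opts$t2_min, 0),
                      upper = c(Inf, opts$t2_max, max(y)))
    if (o$value <= sse[i]) {
      s0[i] <- o$par[1]; t2[i] <- o$par[2]; sse[i] <- o$value
      conv[i] <- o$convergence == 0
    }
  }
  list(s0 = s0, t2 = t2, sse = sse, converged = conv)
}

#' Fit a T2 map over the vessel wall of one slice
#'
#' Fits every voxel inside the outer-wall mask of the ROI; voxels outside
#' are left invalid with reason `"outside_roi"`. The result is a classed
#' `t2map` object with `print`, `summary`, `coef`, `residuals`, `predict`
#' and `plot` methods.
#'
#' @param series An [echo_series()].
#' @param roi A [wall_roi()] whose masks match the series grid.
#' @param options A [t2_fit_options()].
#' @return An object of class `t2map`: matrices `t2`, `s0`, `rsq`, logical
#'   `valid`, character `reason`, plus the `roi`, `echo_times` and slice
#'   geometry.
#' @export
fit_slice <- function(series, roi, options = t2_fit_options()) {
  stopifnot(inherits(series, "echo_series"), inherits(roi, "wall_roi"))
  d <- dim(series$data)
  if (!all(dim(roi$outer_mask) == d[1:2]))
    stop2("ROI masks do not match the series grid")
  idx <- which(roi$outer_mask)
  if (length(idx) == 0L) stop2("empty ROI: outer-wall mask has no voxels")
  Y <- matrix(series$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  fit <- .fit_one_batch(Y, series$echo_times, options)

  blank <- matrix(NA_real_, d[1], d[2])
  t2 <- blank; s0 <- blank; rsq <- blank
  valid <- matrix(FALSE, d[1], d[2])
  reason <- matrix("outside_roi", d[1], d[2])
  t2[idx] <- fit$t2; s0[idx] <- fit$s0; rsq[idx] <- fit$rsq
  valid[idx] <- fit$valid; reason[idx] <- fit$reason
  structure(list(t2 = t2, s0 = s0, rsq = rsq, valid = valid, reason = reason,
                 roi = roi, echo_times = series$echo_times,
                 slice_index = series$slice_index,
                 voxel_area = series$voxel_area,
                 slice_thickness = series$slice_thickness,
                 options = options),
            class = "t2map")
}

#' Fit T2 maps for several slices in one solver call
#'
#' Stacks the ROI voxels of all slices into a single batched
#' Levenberg-Marquardt run (all slices must share one echo train), then
#' unpacks per-slice `t2map` objects. Results are identical to calling
#' [fit_slice()] slice by slice; only the amortized cost differs.
#'
#' @param series_list List of [echo_series()] with identical `echo_times`.
#' @param roi_list List of matching [wall_roi()] objects.
#' @param options A [t2_fit_options()].
#' @return List of `t2map` objects.
#' @export
fit_slices <- function(series_list, roi_list, options = t2_fit_options()) {
  if (length(series_list) != length(roi_list))
    stop2("'series_list' and 'roi_list' must have equal length")
  if (!length(series_list)) return(list())
  te <- series_list[[1]]$echo_times
  for (s in series_list)
    if (!isTRUE(all.equal(s$echo_times, te)))
      stop2("all series must share one echo train")
  idxs <- lapply(roi_list, function(r) which(r$outer_mask))
  Ys <- mapply(function(s, idx) {
    d <- dim(s$data)
    matrix(s$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  }, series_list, idxs, SIMPLIFY = FALSE)
  fit <- .fit_one_batch(do.call(rbind, Ys), te, options)
  ends <- cumsum(vapply(idxs, length, 0L))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]; roi <- roi_list[[i]]; idx <- idxs[[i]]
    take <- function(v) v[starts[i]:ends[i]]
    d <- dim(s$data)
    blank <- matrix(NA_real_, d[1], d[2])
    t2 <- blank; s0 <- blank; rsq <- blank
    valid <- matrix(FALSE, d[1], d[2])
    reason <- matrix("outside_roi", d[1], d[2])
    t2[idx] <- take(fit$t2); s0[idx] <- take(fit$s0)
    rsq[idx] <- take(fit$rsq); valid[idx] <- take(fit$valid)
    reason[idx] <- take(fit$reason)
    structure(list(t2 = t2, s0 = s0, rsq = rsq, valid = valid,
                   reason = reason, roi = roi, echo_times = te,
                   slice_index = s$slice_index, voxel_area = s$voxel_area,
                   slice_thickness = s$slice_thickness, options = options),
              class = "t2map")
  })
}

#' @export
print.t2map <- function(x, ...) {
  nw <- sum(x$roi$wall_mask)
  nv <- sum(x$valid & x$roi$wall_mask)
  cat(sprintf("T2 map, slice %d: %d wall voxels, %d valid fits (%.1f%%)\n",
              x$slice_index, nw, nv, 100 * nv / max(1, nw)))
  if (nv) {
    t2w <- x$t2[x$valid & x$roi$wall_mask]
    cat(sprintf("  wall T2: median %.1f ms, IQR %.1f-%.1f ms\n",
                stats::median(t2w), stats::quantile(t2w, 0.25),
                stats::quantile(t2w, 0.75)))
  }
  invisible(x)
}

#' @export
summary.t2map <- function(object, ...) {
  w <- object$roi$wall_mask
  v <- object$valid & w
  out <- list(slice_index = object$slice_index,
              n_wall = sum(w), n_valid = sum(v),
              reasons = table(object$reason[w & !object$valid]),
              t2_quartiles = if (any(v)) stats::quantile(object$t2[v]) else NULL,
              median_rsq = if (any(v)) stats::median(object$rsq[v]) else NA_real_)
  class(out) <- "summary.t2map"
  out
}

#' @export
print.summary.t2map <- function(x, ...) {
  cat(sprintf("T2 map summary (slice %d)\n", x$slice_index))
  cat(sprintf("  wall voxels: %d, valid fits: %d, median R^2: %.3f\n",
              x$n_wall, x$n_valid, x$median_rsq))
  if (length(x$reasons))
    cat("  invalid:", paste(sprintf("%s=%d", names(x$reasons), x$reasons),
                            collapse = ", "), "\n")
  if (!is.null(x$t2_quartiles))
    cat("  wall T2 quartiles (ms):",
        paste(sprintf("%.1f", x$t2_quartiles), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.t2map <- function(object, ...) {
  idx <- which(object$valid)
  data.frame(voxel = idx, t2 = object$t2[idx], s0 = object$s0[idx],
             rsq = object$rsq[idx])
}

#' Predicted echo signals from a fitted T2 map
#'
#' @param object A `t2map`.
#' @param echo_times Echo times (ms) at which to evaluate the fitted decay;
#'   defaults to the acquisition's.
#' @param ... Unused.
#' @return Array grid x grid x length(echo_times); `NA` outside valid fits.
#' @export
predict.t2map <- function(object, echo_times = object$echo_times, ...) {
  d <- dim(object$t2)
  out <- array(NA_real_, c(d, length(echo_times)))
  idx <- which(object$valid)
  for (k in seq_along(echo_times)) {
    plane <- matrix(NA_real_, d[1], d[2])
    plane[idx] <- object$s0[idx] * exp(-echo_times[k] / object$t2[idx])
    out[, , k] <- plane
  }
  out
}

#' Residuals of a fitted T2 map against an echo series
#'
#' @param object A `t2map`.
#' @param series The [echo_series()] the map was fitted to.
#' @param ... Unused.
#' @return Array of observed minus fitted signals.
#' @export
residuals.t2map <- function(object, series, ...) {
  stopifnot(inherits(series, "echo_series"))
  series$data - predict(object, series$echo_times)
}

#' Display a T2 map
#'
#' @param x A `t2map`.
#' @param zlim T2 display range, ms.
#' @param ... Passed to [graphics::image()].
#' @export
plot.t2map <- function(x, zlim = c(0, 150), ...) {
  z <- x$t2
  z[!x$valid] <- NA
  z <- pmin(pmax(z, zlim[1]), zlim[2])
  graphics::image(z, zlim = zlim, asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("T2 map (slice %d)", x$slice_index), ...)
  invisible(x)
}
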