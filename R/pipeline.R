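# From a 4D label/control pCASL run to CBF maps, ROI profiles, baseline CBF
# and CVR.

#' 4D ASL time series
#'
#' Container for a pCASL run: a 4D intensity array with alternating label
#' and control frames, frame timing, and the CO2 challenge window.
#'
#' @param volumes 4D array (x, y, z, frame); even number of frames.
#' @param frame_duration Duration of one frame, seconds.
#' @param label_first `TRUE` when odd frames are label, `FALSE` when odd
#'   frames are control.
#' @param co2_on,co2_off CO2 challenge window, seconds from run start.
#' @param voxel_dims Voxel dimensions, mm (length 3).
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(volumes, frame_duration, label_first = TRUE,
                       co2_on = 420, co2_off = 840,
                       voxel_dims = c(0.225, 0.225, 1.5)) {
  stopifnot(length(dim(volumes)) == 4)
  n <- dim(volumes)[4]
  if (n %% 2 != 0) stop("frame count must be even (label/control pairs)")
  if (any(voxel_dims <= 0)) stop("voxel_dims must be > 0")
  run_end <- n * frame_duration
  if (!(co2_on < co2_off && co2_off <= run_end + 1e-9))
    stop("need co2_on < co2_off <= run end")
  structure(list(volumes = volumes, frame_duration = frame_duration,
                 label_first = label_first, co2_on = co2_on,
                 co2_off = co2_off, voxel_dims = voxel_dims),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("ASL series: %d x %d x %d voxels, %d frames (%d pairs)\n",
              d[1], d[2], d[3], d[4], d[4] / 2))
  cat(sprintf("  frame duration %g s, %s first, CO2 window %g-%g s\n",
              x$frame_duration, if (x$label_first) "label" else "control",
              x$co2_on, x$co2_off))
  invisible(x)
}

#' Pairwise label/control subtraction
#'
#' Collapses alternating label/control frames into one control-minus-label
#' difference volume per pair, halving the number of time points. A run of
#' 180 frames yields 90 difference dynamics.
#'
#' @param series An [asl_series()], or a numeric vector of alternating
#'   frame values (a single-voxel profile).
#' @return For an `asl_series`: a list with `delta_m` (4D array, one volume
#'   per pair), `times` (start time of each pair-dynamic, s) and
#'   `dyn_duration` (s). For a vector: a numeric vector of differences.
#' @export
pairwise_delta_m <- function(series) {
  if (is.numeric(series) && is.null(dim(series))) {
    n <- length(series)
    if (n %% 2 != 0) stop("frame count must be even")
    a <- series[seq(1, n, by = 2)]
    b <- series[seq(2, n, by = 2)]
    return(b - a)  # assumes label first: control - label
  }
  stopifnot(inherits(series, "asl_series"))
  n <- dim(series$volumes)[4]
  odd <- series$volumes[, , , seq(1, n, by = 2), drop = FALSE]
  even <- series$volumes[, , , seq(2, n, by = 2), drop = FALSE]
  dm <- if (series$label_first) even - odd else odd - even
  dyn <- 2 * series$frame_duration
  list(delta_m = dm, times = (seq_len(n / 2) - 1) * dyn, dyn_duration = dyn)
}

#' Voxelwise CBF quantification of a difference series
#'
#' Applies [quantify_cbf()] to every voxel and dynamic of a difference
#' series, using per-voxel T1t/M0t maps (or scalars). Voxels outside the
#' mask become `NA`.
#'
#' @param delta_m 4D difference array (x, y, z, dynamic).
#' @param t1_map,m0_map 3D maps on the same grid, or scalars.
#' @param acq An [acq_params()] object.
#' @param mask Optional logical/0-1 3D array; voxels outside are NA.
#' @return 4D CBF array, mL/100 g/min.
#' @export
cbf_series <- function(delta_m, t1_map, m0_map, acq, mask = NULL) {
  stopifnot(inherits(acq, "acq_params"), length(dim(delta_m)) == 4)
  dims <- dim(delta_m)
  bolus <- 1 - exp(-acq$tau / t1_map)
  denom <- 2 * acq$alpha * t1_map * m0_map * bolus
  scale <- acq$lambda_bbp * exp(acq$pld / acq$t1_blood) * CBF_UNIT_FACTOR / denom
  scale_arr <- if (length(scale) == 1) scale
               else array(rep(scale, dims[4]), dims)
  out <- delta_m * scale_arr
  if (!is.null(mask)) {
    nam <- array(rep(!as.logical(mask), dims[4]), dims)
    out[nam] <- NA_real_
  }
  out
}

#' Sliding-window moving-average filter
#'
#' Centered moving average of odd width; at the edges the window shrinks
#' symmetrically to the available points.
#'
#' @param profile Numeric vector.
#' @param window Odd window width, <= length(profile).
#' @return Filtered vector, same length.
#' @examples
#' sliding_window_filter(c(1, 2, 3, 4, 5), 3)   # 1.5 2 3 4 4.5
#' @export
sliding_window_filter <- function(profile, window = 3) {
  n <- length(profile)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > n) stop("window exceeds profile length")
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(profile[lo:hi])
  }, numeric(1))
}

#' Indices of the pre-CO2 baseline window
#'
#' The baseline window is the last `n_reps` difference dynamics that start
#' before CO2 onset.
#'
#' @param times Start time of each dynamic, seconds.
#' @param co2_on CO2 onset, seconds from run start.
#' @param n_reps Number of dynamics in the window (default 20).
#' @return Integer indices into the profile (1-based).
#' @export
baseline_window <- function(times, co2_on, n_reps = 20) {
  pre <- which(times < co2_on)
  if (length(pre) < n_reps)
    stop("fewer than ", n_reps, " dynamics before CO2 onset")
  utils::tail(pre, n_reps)
}

#' Baseline CBF from a time profile
#'
#' Average of the last `n_reps` dynamics before CO2 onset.
#'
#' @param profile CBF per dynamic, mL/100 g/min.
#' @param times Start time of each dynamic, seconds.
#' @param co2_on CO2 onset, seconds.
#' @param n_reps Window length in dynamics (default 20).
#' @return Baseline CBF, mL/100 g/min.
#' @export
baseline_cbf <- function(profile, times, co2_on, n_reps = 20) {
  stopifnot(length(profile) == length(times))
  mean(profile[baseline_window(times, co2_on, n_reps)])
}

#' Cerebrovascular reactivity from a time profile
#'
#' Percent CBF change between the hypercapnic plateau (average of the last
#' `n_reps` dynamics inside the CO2 window) and baseline (average of the
#' last `n_reps` dynamics before CO2 onset):
#' `100 * (plateau - baseline) / baseline`.
#'
#' @inheritParams baseline_cbf
#' @param co2_off CO2 offset, seconds.
#' @return CVR in percent; `NA` with a warning when the baseline is zero.
#' @export
cvr <- function(profile, times, co2_on, co2_off, n_reps = 20) {
  stopifnot(length(profile) == length(times))
  base <- baseline_cbf(profile, times, co2_on, n_reps)
  during <- which(times >= co2_on & times < co2_off)
  if (length(during) < n_reps)
    stop("fewer than ", n_reps, " dynamics inside the CO2 window")
  plateau <- mean(profile[utils::tail(during, n_reps)])
  if (!is.finite(base) || base == 0) {
    warning("zero baseline: CVR undefined")
    return(NA_real_)
  }
  100 * (plateau - base) / base
}

#' ROI mean time profile
#'
#' Mean over the mask for each dynamic; `NA` voxels (masked/flagged) are
#' excluded, never zero-filled.
#'
#' @param series 4D array (x, y, z, dynamic).
#' @param mask Logical/0-1 3D array, non-empty, same spatial grid.
#' @return Numeric vector, one value per dynamic.
#' @export
roi_profile <- function(series, mask) {
  stopifnot(length(dim(series)) == 4)
  m <- as.logical(mask)
  if (!any(m)) stop("empty mask")
  if (!all(dim(mask) == dim(series)[1:3]))
    stop("mask grid does not match series")
  nd <- dim(series)[4]
  flat <- matrix(series, ncol = nd)
  colMeans(flat[m, , drop = FALSE], na.rm = TRUE)
}

#' Brain volume from a mask
#'
#' Number of voxels in the volume of interest times the voxel volume.
#'
#' @param mask Logical/0-1 array.
#' @param voxel_dims Voxel dimensions, mm (length 3).
#' @return Volume in mm^3.
#' @export
brain_volume <- function(mask, voxel_dims) {
  if (any(voxel_dims <= 0)) stop("voxel_dims must be > 0")
  sum(as.logical(mask)) * prod(voxel_dims)
}

#' Normalize a laser Doppler flowmetry trace
#'
#' Filters the trace with a sliding window and divides by the mean signal
#' over the initial baseline period, yielding a dimensionless profile with
#' baseline mean 1.
#'
#' @param profile LDF signal per sample.
#' @param times Sample times, seconds.
#' @param baseline_duration Baseline period from run start, seconds
#'   (default 420 s = 7 min).
#' @param window Sliding-window width (odd; default 3).
#' @return Normalized profile.
#' @export
ldf_normalize <- function(profile, times, baseline_duration = 420,
                          window = 3) {
  stopifnot(length(profile) == length(times))
  filt <- sliding_window_filter(profile, window)
  base <- mean(filt[times < baseline_duration])
  if (!is.finite(base) || base == 0) stop("zero/undefined LDF baseline")
  filt / base
}

#' Rigid frame alignment (identity stub)
#'
#' Placeholder for motion correction of the frame stack. Simulated data are
#' motion-free, so the default implementation returns the series unchanged;
#' it exists so that a registration step can be slotted into the pipeline
#' without changing downstream code.
#'
#' @param series An [asl_series()].
#' @return The series, unchanged.
#' @export
align_frames <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  series
}

#' Full perfusion quantification of one run
#'
#' Runs the complete processing chain on a 4D pCASL run: frame alignment
#' (identity on simulated data), pairwise label/control subtraction,
#' voxelwise kinetic-model quantification, per-ROI profile extraction,
#' sliding-window filtering, and baseline-CBF / CVR computation per ROI.
#'
#' @param series An [asl_series()].
#' @param t1_map,m0_map Per-voxel T1t/M0t maps (3D) or scalars.
#' @param acq An [acq_params()] object.
#' @param rois Named list of masks (logical/0-1 3D arrays).
#' @param filter_window Sliding-window width for the profiles (default 3).
#' @param n_reps Baseline/plateau window length in dynamics (default 20).
#' @return An object of class `perfusion_result`: `cbf_maps` (4D array),
#'   `times`, per-ROI `profiles` (filtered), `baseline_cbf`, `cvr`,
#'   `roi_volumes` (mm^3).
#' @export
quantify_run <- function(series, t1_map, m0_map, acq, rois,
                         filter_window = 3, n_reps = 20) {
  stopifnot(inherits(series, "asl_series"), is.list(rois), length(rois) > 0)
  series <- align_frames(series)
  pairs <- pairwise_delta_m(series)
  maps <- cbf_series(pairs$delta_m, t1_map, m0_map, acq)
  profiles <- lapply(rois, function(m) {
    sliding_window_filter(roi_profile(maps, m), filter_window)
  })
  base <- vapply(profiles, baseline_cbf, numeric(1),
                 times = pairs$times, co2_on = series$co2_on, n_reps = n_reps)
  reactivity <- vapply(profiles, cvr, numeric(1), times = pairs$times,
                       co2_on = series$co2_on, co2_off = series$co2_off,
                       n_reps = n_reps)
  vols <- vapply(rois, brain_volume, numeric(1),
                 voxel_dims = series$voxel_dims)
  structure(list(cbf_maps = maps, times = pairs$times, profiles = profiles,
                 baseline_cbf = base, cvr = reactivity, roi_volumes = vols,
                 co2_on = series$co2_on, co2_off = series$co2_off),
            class = "perfusion_result")
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf("perfusion result: %d dynamics, %d ROIs\n",
              length(x$times), length(x$profiles)))
  for (nm in names(x$profiles)) {
    cat(sprintf("  %-14s baseline CBF %6.1f mL/100 g/min   CVR %6.1f %%\n",
                nm, x$baseline_cbf[[nm]], x$cvr[[nm]]))
  }
  invisible(x)
}

#' @export
summary.perfusion_result <- function(object, ...) {
  data.frame(roi = names(object$profiles),
             baseline_cbf = as.numeric(object$baseline_cbf),
             cvr_pct = as.numeric(object$cvr),
             volume_mm3 = as.numeric(object$roi_volumes),
             row.names = NULL)
}

#' @export
plot.perfusion_result <- function(x, rois = names(x$profiles), ...) {
  ylim <- range(unlist(x$profiles[rois]), na.rm = TRUE)
  plot(NULL, xlim = range(x$times), ylim = ylim, xlab = "time (s)",
       ylab = "CBF (mL/100 g/min)", main = "ROI CBF time profiles", ...)
  cols <- seq_along(rois) + 1
  for (i in seq_along(rois))
    graphics::lines(x$times, x$profiles[[rois[i]]], col = cols[i])
  graphics::abline(v = c(x$co2_on, x$co2_off), lty = 3)
  graphics::legend("topleft", legend = rois, col = cols, lty = 1, bty = "n")
  invisible(x)
}
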