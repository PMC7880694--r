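# NIfTI and tabular I/O plus provenance-stamped reports. NIfTI is the single
# image format; sidecar times are in seconds, kinetic math in milliseconds.

#' Read a 4D ASL run from NIfTI + sidecar
#'
#' @param path Path to a 4D NIfTI file (alternating label/control frames).
#' @param sidecar Path to the JSON/YAML acquisition sidecar
#'   (see [read_sidecar()]).
#' @param label_first Frame order flag (not carried in the sidecar).
#' @return A list with `series` (an [asl_series()]) and `acq`
#'   (an [acq_params()]).
#' @export
read_asl_nifti <- function(path, sidecar, label_first = TRUE) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  meta <- read_sidecar(sidecar)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stop("expected a 4D NIfTI, got ", length(dim(arr)), " dimensions")
  if (dim(arr)[4] != meta$n_dynamics)
    stop("frame count (", dim(arr)[4], ") does not match sidecar n_dynamics (",
         meta$n_dynamics, ")")
  pix <- RNifti::pixdim(img)
  series <- asl_series(arr,
                       frame_duration = meta$scan_duration_s / meta$n_dynamics,
                       label_first = label_first,
                       co2_on = meta$co2_on_s, co2_off = meta$co2_off_s,
                       voxel_dims = pix[1:3])
  list(series = series, acq = meta$acq)
}

#' Write a 4D ASL run to NIfTI + sidecar
#'
#' @param series An [asl_series()].
#' @param acq An [acq_params()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar Output sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
write_asl_nifti <- function(series, acq, path, sidecar = NULL) {
  stopifnot(inherits(series, "asl_series"))
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  img <- RNifti::asNifti(series$volumes)
  RNifti::pixdim(img) <- c(series$voxel_dims, series$frame_duration)
  RNifti::writeNifti(img, path)
  n <- dim(series$volumes)[4]
  write_sidecar(acq, n, n * series$frame_duration,
                series$co2_on, series$co2_off, sidecar)
  invisible(path)
}

#' Read ROI masks from NIfTI
#'
#' Reads a 4D NIfTI with one binary mask per volume (or a 3D label image)
#' and returns named logical arrays.
#'
#' @param path NIfTI path.
#' @param names ROI names; for a label image, name `i` maps to label `i`.
#' @return Named list of logical arrays.
#' @export
read_roi_nifti <- function(path, names) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4) {
    stopifnot(dim(arr)[4] == length(names))
    out <- lapply(seq_along(names), function(i) arr[, , , i] > 0)
  } else {
    out <- lapply(seq_along(names), function(i) arr == i)
  }
  stats::setNames(out, names)
}

#' Write a cohort endpoint table to CSV
#'
#' @param table Cohort table (see [simulate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an analysis report with provenance
#'
#' Serializes per-ROI results as CSV (profiles) and JSON (summary); every
#' output embeds the seed and a hash of the configuration so a run can be
#' reproduced bit-for-bit.
#'
#' @param result A `perfusion_result` (from [quantify_run()]).
#' @param outdir Output directory, created if needed.
#' @param config List of run configuration values to hash into provenance.
#' @param seed The RNG seed used for the run.
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(result, outdir, config = list(), seed = NA) {
  stopifnot(inherits(result, "perfusion_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                    seq_len(nchar(cfg_json))) %% 0xffffffff)
  prov <- list(config_hash = cfg_hash, seed = seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  paths <- character()
  for (nm in names(result$profiles)) {
    p <- file.path(outdir, paste0("profile_", nm, ".csv"))
    con <- file(p, "w")
    writeLines(sprintf("# config_hash=%s seed=%s", cfg_hash, seed), con)
    utils::write.csv(data.frame(dynamic_index = seq_along(result$times),
                                time_s = result$times,
                                cbf = result$profiles[[nm]]),
                     con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  sm <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(provenance = prov,
         rois = lapply(stats::setNames(names(result$profiles),
                                       names(result$profiles)),
                       function(nm) list(
                         baseline_cbf = result$baseline_cbf[[nm]],
                         cvr = result$cvr[[nm]],
                         volume_mm3 = result$roi_volumes[[nm]]))),
    sm, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sm))
}

#' Write a CBF (or other) map series to NIfTI
#'
#' @param maps 3D or 4D array.
#' @param voxel_dims Voxel size, mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(maps, voxel_dims, path) {
  img <- RNifti::asNifti(maps)
  RNifti::pixdim(img) <- c(voxel_dims, rep(1, length(dim(maps)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
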