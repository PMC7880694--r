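#' Acquisition parameters for pCASL quantification
#'
#' Bundles the constants that enter the kinetic-model quantification:
#' labeling duration, post-labeling delay, blood T1, the blood-brain
#' partition coefficient and the labeling efficiency. All times are in
#' milliseconds; `lambda_bbp` is in mL/g. Defaults correspond to a 7 T
#' mouse protocol: tau = 3000 ms, PLD = 300 ms, T1 of blood 2230 ms,
#' lambda = 0.9 mL/g, alpha = 0.9.
#'
#' @param tau Labeling duration in ms (> 0).
#' @param pld Post-labeling delay in ms (>= 0).
#' @param t1_blood Longitudinal relaxation time of arterial blood in ms.
#' @param lambda_bbp Blood-brain partition coefficient in mL/g.
#' @param alpha Labeling (inversion) efficiency, a fraction in (0, 1].
#' @return An object of class `acq_params`.
#' @examples
#' acq_params()
#' acq_params(tau = 3000, pld = 300, alpha = 0.85)
#' @export
acq_params <- function(tau = 3000, pld = 300, t1_blood = 2230,
                       lambda_bbp = 0.9, alpha = 0.9) {
  stopifnot(is.numeric(tau), is.numeric(pld), is.numeric(t1_blood),
            is.numeric(lambda_bbp), is.numeric(alpha))
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0 ms")
  if (!is.finite(pld) || pld < 0) stop("pld must be >= 0 ms")
  if (!is.finite(t1_blood) || t1_blood <= 0) stop("t1_blood must be > 0 ms")
  if (!is.finite(lambda_bbp) || lambda_bbp <= 0) stop("lambda_bbp must be > 0 mL/g")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(tau = tau, pld = pld, t1_blood = t1_blood,
                 lambda_bbp = lambda_bbp, alpha = alpha),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("pCASL acquisition parameters\n")
  cat(sprintf("  tau      : %g ms (labeling duration)\n", x$tau))
  cat(sprintf("  PLD      : %g ms (post-labeling delay)\n", x$pld))
  cat(sprintf("  T1 blood : %g ms\n", x$t1_blood))
  cat(sprintf("  lambda   : %g mL/g\n", x$lambda_bbp))
  cat(sprintf("  alpha    : %g\n", x$alpha))
  invisible(x)
}

#' Tissue parameters for quantification
#'
#' Tissue T1 and equilibrium magnetization, typically obtained from an
#' inversion-recovery fit ([fit_inversion_recovery()]). The default
#' T1 of 1700 ms is representative of mouse brain tissue at 7 T and is
#' used by the simulators when no fit is supplied.
#'
#' @param t1_tissue Longitudinal relaxation time of tissue in ms (> 0).
#' @param m0_tissue Equilibrium tissue magnetization, arbitrary units (> 0).
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t1_tissue = 1700, m0_tissue = 1000) {
  if (!is.numeric(t1_tissue) || !is.finite(t1_tissue) || t1_tissue <= 0)
    stop("t1_tissue must be > 0 ms")
  if (!is.numeric(m0_tissue) || !is.finite(m0_tissue) || m0_tissue <= 0)
    stop("m0_tissue must be > 0")
  structure(list(t1_tissue = t1_tissue, m0_tissue = m0_tissue),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("tissue: T1t = %g ms, M0t = %g a.u.\n", x$t1_tissue, x$m0_tissue))
  invisible(x)
}

#' Ground-truth perfusion state
#'
#' Holds a true cerebral blood flow and arterial transit time, used by the
#' forward kinetic model and the simulators.
#'
#' @param cbf Cerebral blood flow in mL/100 g/min (>= 0).
#' @param att Arterial transit time in ms (>= 0).
#' @return An object of class `perfusion_truth`.
#' @export
perfusion_truth <- function(cbf, att = 0) {
  if (!is.numeric(cbf) || any(!is.finite(cbf)) || any(cbf < 0))
    stop("cbf must be >= 0")
  if (!is.numeric(att) || any(!is.finite(att)) || any(att < 0))
    stop("att must be >= 0 ms")
  structure(list(cbf = cbf, att = att), class = "perfusion_truth")
}

#' Read an acquisition sidecar file
#'
#' Reads a JSON or YAML sidecar describing a pCASL run. Times in the sidecar
#' are in the units indicated by their key suffix (`_ms` or `_s`); kinetic
#' constants are returned as an [acq_params()] object and run timing in
#' seconds.
#'
#' Recognised keys: `tau_ms`, `pld_ms`, `t1_blood_ms`, `lambda_ml_per_g`,
#' `alpha`, `n_dynamics`, `scan_duration_s`, `co2_on_s`, `co2_off_s`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `acq` (an `acq_params`), `n_dynamics`,
#'   `scan_duration_s`, `co2_on_s`, `co2_off_s`.
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path)
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("tau_ms", "pld_ms", "t1_blood_ms", "lambda_ml_per_g", "alpha",
            "n_dynamics", "scan_duration_s", "co2_on_s", "co2_off_s")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("sidecar is missing keys: ", paste(missing, collapse = ", "))
  list(
    acq = acq_params(tau = raw$tau_ms, pld = raw$pld_ms,
                     t1_blood = raw$t1_blood_ms,
                     lambda_bbp = raw$lambda_ml_per_g, alpha = raw$alpha),
    n_dynamics = as.integer(raw$n_dynamics),
    scan_duration_s = raw$scan_duration_s,
    co2_on_s = raw$co2_on_s,
    co2_off_s = raw$co2_off_s
  )
}

#' Write an acquisition sidecar file
#'
#' Inverse of [read_sidecar()]; format is chosen from the file extension.
#'
#' @param acq An [acq_params()] object.
#' @param n_dynamics Number of acquired frames.
#' @param scan_duration_s Total run duration, seconds.
#' @param co2_on_s,co2_off_s CO2 challenge window, seconds from run start.
#' @param path Output path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(acq, n_dynamics, scan_duration_s,
                          co2_on_s, co2_off_s, path) {
  stopifnot(inherits(acq, "acq_params"))
  x <- list(tau_ms = acq$tau, pld_ms = acq$pld, t1_blood_ms = acq$t1_blood,
            lambda_ml_per_g = acq$lambda_bbp, alpha = acq$alpha,
            n_dynamics = n_dynamics, scan_duration_s = scan_duration_s,
            co2_on_s = co2_on_s, co2_off_s = co2_off_s)
  if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
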