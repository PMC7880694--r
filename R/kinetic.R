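# Buxton general kinetic model: quantification (inverse) and inflow (forward).
# All kinetic math is in ms; CBF is mL/100 g/min at the user surface and
# mL/g/ms internally (factor 6e6).

CBF_UNIT_FACTOR <- 6.0e6  # mL/g/ms -> mL/100 g/min

#' Quantify CBF from a label/control signal difference
#'
#' Converts a pCASL signal difference into absolute cerebral blood flow via
#' the single-compartment general kinetic model:
#' \deqn{CBF = \frac{\lambda \, \Delta M \, e^{PLD/T_{1b}}}
#'   {2 \alpha T_{1t} M_{0t} (1 - e^{-\tau/T_{1t}})}}
#' evaluated in mL/g/ms and converted to mL/100 g/min. The expression is
#' linear in `delta_m`, so it applies equally to scalars, time profiles and
#' voxel maps.
#'
#' @param delta_m Control-minus-label signal difference, arbitrary units.
#'   May be a vector or array; `NA` propagates.
#' @param tissue A [tissue_params()] object (or list with `t1_tissue`,
#'   `m0_tissue`).
#' @param acq An [acq_params()] object.
#' @return CBF in mL/100 g/min, same shape as `delta_m`.
#' @examples
#' acq <- acq_params()
#' tis <- tissue_params(t1_tissue = 1700, m0_tissue = 1000)
#' quantify_cbf(10, tis, acq)   # deltaM of 1% of M0
#' @seealso [gkm_delta_m()] for the forward model it inverts.
#' @export
quantify_cbf <- function(delta_m, tissue, acq) {
  stopifnot(inherits(acq, "acq_params"))
  if (!is.numeric(delta_m)) stop("delta_m must be numeric")
  if (any(is.nan(delta_m) | is.infinite(delta_m)))
    stop("delta_m contains non-finite values")
  bolus <- 1 - exp(-acq$tau / tissue$t1_tissue)
  denom <- 2 * acq$alpha * tissue$t1_tissue * tissue$m0_tissue * bolus
  if (!is.finite(denom) || denom <= .Machine$double.xmin)
    stop("degenerate acquisition: tau/T1t too small, denominator underflows")
  cbf_ml_g_ms <- acq$lambda_bbp * delta_m * exp(acq$pld / acq$t1_blood) / denom
  cbf_ml_g_ms * CBF_UNIT_FACTOR
}

#' Forward kinetic model: label inflow curve
#'
#' Predicts the control-minus-label difference signal at time `t` after
#' label onset for a single-compartment inflow model: no signal before the
#' label arrives (`t < att`), accumulation with the tissue T1 while the
#' bolus flows in (`att <= t < att + tau`), and decay with the blood T1
#' afterwards. Label magnetization decays with the blood T1 during transit
#' and after the bolus has been delivered, so that at `att = 0` and
#' `t = tau + PLD` the curve is the exact algebraic inverse of
#' [quantify_cbf()].
#'
#' @param truth A [perfusion_truth()] object (CBF in mL/100 g/min, ATT ms).
#' @param tissue A [tissue_params()] object.
#' @param acq An [acq_params()] object; `acq$tau` is the labeling duration
#'   of the bolus being modeled.
#' @param t Time since label onset, ms (vectorised, must be >= 0).
#' @return Difference signal in the units of `m0_tissue`.
#' @examples
#' tr <- perfusion_truth(cbf = 120, att = 200)
#' gkm_delta_m(tr, tissue_params(), acq_params(), t = c(100, 1000, 3300))
#' @export
gkm_delta_m <- function(truth, tissue, acq, t) {
  stopifnot(inherits(acq, "acq_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0 ms")
  cbf_ml_g_ms <- truth$cbf / CBF_UNIT_FACTOR
  att <- truth$att
  amp <- 2 * acq$alpha * tissue$m0_tissue * cbf_ml_g_ms / acq$lambda_bbp
  out <- numeric(length(t))
  rising <- t >= att & t < att + acq$tau
  decayed <- t >= att + acq$tau
  if (any(rising)) {
    out[rising] <- amp * tissue$t1_tissue *
      (1 - exp(-(t[rising] - att) / tissue$t1_tissue)) *
      exp(-att / acq$t1_blood)
  }
  if (any(decayed)) {
    out[decayed] <- amp * tissue$t1_tissue *
      (1 - exp(-acq$tau / tissue$t1_tissue)) *
      exp(-att / acq$t1_blood) *
      exp(-(t[decayed] - att - acq$tau) / acq$t1_blood)
  }
  out
}

#' Hypercapnia block-design CBF profile
#'
#' Drives a simulated CBF time course through a CO2 challenge: baseline
#' before `t_on`, mono-exponential approach to
#' `baseline * (1 + cvr_pct/100)` during the challenge, and mono-exponential
#' return to baseline after `t_off`.
#'
#' @param baseline_cbf Baseline CBF, mL/100 g/min.
#' @param cvr_pct Plateau CBF change during the challenge, percent.
#' @param t_on,t_off Challenge window, seconds from run start (`t_on < t_off`).
#' @param tau_response Response time constant, seconds (> 0).
#' @param times Evaluation times, seconds.
#' @return CBF at `times`, mL/100 g/min.
#' @examples
#' hypercapnia_cbf_profile(100, 30, t_on = 420, t_off = 840,
#'                         tau_response = 30, times = c(0, 450, 840, 900))
#' @export
hypercapnia_cbf_profile <- function(baseline_cbf, cvr_pct, t_on, t_off,
                                    tau_response, times) {
  if (!is.finite(tau_response) || tau_response <= 0)
    stop("tau_response must be > 0 s")
  if (t_on >= t_off) stop("t_on must be < t_off")
  plateau <- baseline_cbf * (1 + cvr_pct / 100)
  out <- rep(baseline_cbf, length(times))
  during <- times >= t_on & times < t_off
  out[during] <- plateau + (baseline_cbf - plateau) *
    exp(-(times[during] - t_on) / tau_response)
  after <- times >= t_off
  if (any(after)) {
    at_off <- plateau + (baseline_cbf - plateau) *
      exp(-(t_off - t_on) / tau_response)
    out[after] <- baseline_cbf + (at_off - baseline_cbf) *
      exp(-(times[after] - t_off) / tau_response)
  }
  out
}
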