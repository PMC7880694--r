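# Synthetic-data generators: digital phantom pCASL runs, IR series,
# time-encoded pCASL acquisitions, LDF traces and multi-mouse cohort tables,
# all with known ground truth and reproducible under a seed.

#' Digital perfusion phantom
#'
#' A small 3D phantom with three disjoint tissue regions on a brain-like
#' oval: a dorsal cortical band, a central thalamic blob, and the remaining
#' mid-brain tissue. Each region carries its own ground-truth perfusion
#' state (CBF, CVR, ATT) and tissue parameters (T1t, M0t). Voxels outside
#' the oval are empty background.
#'
#' Default truths are representative of an adult mouse under isoflurane at
#' 7 T: a strongly reactive cortex and lower, less reactive deep tissue,
#' with transit times of roughly 200 ms.
#'
#' @param dims Grid dimensions (default 16 x 16 x 3).
#' @param voxel_dims Voxel size, mm.
#' @param regions Named list; each element a list with `cbf`
#'   (mL/100 g/min), `cvr` (%), `att` (ms), `t1_tissue` (ms), `m0_tissue`.
#' @param noise_sd Frame noise standard deviation as a fraction of M0t.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @return An object of class `phantom_spec` with the region truth, label
#'   arrays and masks.
#' @export
phantom_spec <- function(dims = c(16, 16, 3),
                         voxel_dims = c(0.225, 0.225, 1.5),
                         regions = list(
                           cortex = list(cbf = 155, cvr = 30, att = 180,
                                         t1_tissue = 1700, m0_tissue = 1000),
                           thalamus = list(cbf = 120, cvr = 15, att = 230,
                                           t1_tissue = 1750, m0_tissue = 1000),
                           midbrain_rest = list(cbf = 100, cvr = 10, att = 206,
                                                t1_tissue = 1700,
                                                m0_tissue = 1000)),
                         noise_sd = 0.0025, noise_model = "gaussian") {
  stopifnot(length(dims) == 3, all(dims[1:2] >= 8), dims[3] >= 1,
            noise_sd >= 0)
  noise_model <- match.arg(noise_model, c("gaussian", "rician"))
  lab <- array(0L, dims)
  cx <- (seq_len(dims[1]) - (dims[1] + 1) / 2) / (dims[1] / 2)
  cy <- (seq_len(dims[2]) - (dims[2] + 1) / 2) / (dims[2] / 2)
  r2 <- outer(cx^2, cy^2, `+`)
  oval <- r2 <= 0.9
  for (z in seq_len(dims[3])) lab[, , z][oval] <- 3L            # rest
  band <- oval & (matrix(cy, dims[1], dims[2], byrow = TRUE) > 0.35)
  for (z in seq_len(dims[3])) lab[, , z][band] <- 1L            # cortex
  blob <- r2 <= 0.12
  for (z in seq_len(dims[3])) lab[, , z][blob] <- 2L            # thalamus
  masks <- list(cortex = lab == 1L, thalamus = lab == 2L,
                midbrain_rest = lab == 3L)
  names(masks) <- names(regions)[1:3]
  structure(list(dims = dims, voxel_dims = voxel_dims, regions = regions,
                 labels = lab, masks = masks, noise_sd = noise_sd,
                 noise_model = noise_model),
            class = "phantom_spec")
}

#' Analysis masks for a phantom
#'
#' The disjoint region masks plus a `midbrain` union mask covering all
#' tissue (the full mid-brain slice ROI).
#'
#' @param phantom A [phantom_spec()].
#' @return Named list of logical arrays.
#' @export
phantom_masks <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  c(phantom$masks, list(midbrain = phantom$labels > 0L))
}

.add_noise <- function(x, sd_abs, model) {
  if (sd_abs == 0) return(x)
  if (model == "rician")
    sqrt((x + stats::rnorm(length(x), 0, sd_abs))^2 +
           stats::rnorm(length(x), 0, sd_abs)^2)
  else
    x + stats::rnorm(length(x), 0, sd_abs)
}

#' Simulate a hypercapnia pCASL run on a phantom
#'
#' Generates a full 4D label/control pCASL run: each region's CBF follows a
#' hypercapnia block design ([hypercapnia_cbf_profile()]), the difference
#' signal at each pair-dynamic comes from the forward kinetic model
#' evaluated at the readout time `tau + PLD`, control frames are
#' `M0t + noise` and label frames `M0t - deltaM + noise`.
#'
#' @param phantom A [phantom_spec()].
#' @param acq An [acq_params()].
#' @param n_dynamics Number of frames (default 180; must be even).
#' @param scan_duration Run duration, seconds (default 1260 s = 21 min).
#' @param co2_on,co2_off CO2 window, seconds (defaults: minutes 7-14).
#' @param tau_response Hypercapnia response time constant, seconds
#'   (default 30 s; slower anesthesia protocols use larger values).
#' @param seed RNG seed for reproducibility.
#' @param label_first Frame order flag.
#' @return An [asl_series()] with ground truth attached as attribute
#'   `"truth"` (per-region baseline CBF, CVR, ATT).
#' @export
simulate_pcasl_run <- function(phantom, acq = acq_params(),
                               n_dynamics = 180, scan_duration = 1260,
                               co2_on = 420, co2_off = 840,
                               tau_response = 30, seed = 1,
                               label_first = TRUE) {
  stopifnot(inherits(phantom, "phantom_spec"), n_dynamics %% 2 == 0)
  set.seed(seed)
  frame_dur <- scan_duration / n_dynamics
  n_pairs <- n_dynamics / 2
  pair_times <- (seq_len(n_pairs) - 1) * 2 * frame_dur
  dims <- phantom$dims
  vols <- array(0, c(dims, n_dynamics))
  t_readout <- acq$tau + acq$pld
  for (k in seq_along(phantom$regions)) {
    reg <- phantom$regions[[k]]
    m <- phantom$masks[[k]]
    tis <- tissue_params(reg$t1_tissue, reg$m0_tissue)
    cbf_t <- hypercapnia_cbf_profile(reg$cbf, reg$cvr, co2_on, co2_off,
                                     tau_response, pair_times)
    dm_t <- vapply(cbf_t, function(f)
      gkm_delta_m(perfusion_truth(f, reg$att), tis, acq, t_readout),
      numeric(1))
    for (p in seq_len(n_pairs)) {
      ctrl <- array(0, dims); ctrl[m] <- reg$m0_tissue
      labl <- array(0, dims); labl[m] <- reg$m0_tissue - dm_t[p]
      i_lab <- 2 * p - ifelse(label_first, 1, 0)
      i_ctl <- 2 * p - ifelse(label_first, 0, 1)
      vols[, , , i_lab] <- vols[, , , i_lab] + labl
      vols[, , , i_ctl] <- vols[, , , i_ctl] + ctrl
    }
  }
  m0_ref <- max(vapply(phantom$regions, `[[`, numeric(1), "m0_tissue"))
  vols <- array(.add_noise(vols, phantom$noise_sd * m0_ref,
                           phantom$noise_model), dim(vols))
  out <- asl_series(vols, frame_dur, label_first, co2_on, co2_off,
                    phantom$voxel_dims)
  attr(out, "truth") <- lapply(phantom$regions, function(r)
    list(cbf = r$cbf, cvr = r$cvr, att = r$att))
  out
}

#' Simulate an inversion-recovery series on a phantom
#'
#' Signed recovery `M0t * (1 - 2*exp(-TI/T1t))` per region with additive
#' Gaussian noise, returned as magnitude images.
#'
#' @param phantom A [phantom_spec()].
#' @param inversion_times Inversion times, ms.
#' @param seed RNG seed.
#' @return 4D array (x, y, z, TI) of magnitude signals.
#' @export
simulate_ir <- function(phantom,
                        inversion_times = c(50, 150, 300, 600, 1200,
                                            2400, 4800, 8000),
                        seed = 1) {
  stopifnot(inherits(phantom, "phantom_spec"))
  set.seed(seed)
  dims <- phantom$dims
  nt <- length(inversion_times)
  arr <- array(0, c(dims, nt))
  for (k in seq_along(phantom$regions)) {
    reg <- phantom$regions[[k]]
    m <- phantom$masks[[k]]
    s <- reg$m0_tissue * (1 - 2 * exp(-inversion_times / reg$t1_tissue))
    for (i in seq_len(nt)) {
      sl <- arr[, , , i, drop = FALSE]
      dim(sl) <- dims
      sl[m] <- s[i]
      arr[, , , i] <- sl
    }
  }
  m0_ref <- max(vapply(phantom$regions, `[[`, numeric(1), "m0_tissue"))
  abs(array(.add_noise(arr, phantom$noise_sd * m0_ref, "gaussian"),
            dim(arr)))
}

#' Simulate a time-encoded pCASL acquisition
#'
#' For each phantom region, computes the true per-sub-bolus difference
#' signal from the forward kinetic model, encodes it with the Hadamard
#' scheme, and adds frame noise. Under the hypercapnic state, regional CBF
#' is raised by the region's CVR and the transit time shortened by
#' `att_shortening`.
#'
#' @param phantom A [phantom_spec()].
#' @param scheme A [build_scheme()] object.
#' @param acq An [acq_params()].
#' @param state `"baseline"` or `"hypercapnia"`.
#' @param att_shortening ATT reduction under hypercapnia, ms (default 20).
#' @param seed RNG seed.
#' @return Named list per region: `encoded` (one signal per encode),
#'   `truth` (cbf, att used).
#' @export
simulate_te_pcasl <- function(phantom, scheme = build_scheme(7, 250, 50),
                              acq = acq_params(), state = "baseline",
                              att_shortening = 20, seed = 1) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(scheme, "te_scheme"))
  state <- match.arg(state, c("baseline", "hypercapnia"))
  set.seed(seed)
  out <- list()
  for (k in seq_along(phantom$regions)) {
    reg <- phantom$regions[[k]]
    tis <- tissue_params(reg$t1_tissue, reg$m0_tissue)
    cbf <- if (state == "hypercapnia") reg$cbf * (1 + reg$cvr / 100) else reg$cbf
    att <- if (state == "hypercapnia") max(0, reg$att - att_shortening)
           else reg$att
    tru <- perfusion_truth(cbf, att)
    dm <- vapply(seq_along(scheme$effective_plds), function(j) {
      a <- acq; a$tau <- scheme$subbolus_durations[j]
      gkm_delta_m(tru, tis, a,
                  scheme$subbolus_durations[j] + scheme$effective_plds[j])
    }, numeric(1))
    enc <- te_encode(dm, scheme, m0 = reg$m0_tissue)
    enc <- .add_noise(enc, phantom$noise_sd * reg$m0_tissue,
                      phantom$noise_model)
    out[[names(phantom$regions)[k]]] <- list(encoded = enc,
                                             truth = list(cbf = cbf, att = att))
  }
  attr(out, "scheme") <- scheme
  out
}

#' Simulate a laser Doppler flowmetry trace
#'
#' LDF tracks relative perfusion at the cortical surface but with an
#' attenuated hypercapnic response compared to ASL; the default attenuation
#' of 0.5 reflects ASL CVR being roughly twice the LDF response.
#'
#' @param cbf_profile True CBF time course, mL/100 g/min.
#' @param times Sample times, seconds.
#' @param attenuation Fraction of the relative CBF change LDF sees.
#' @param noise_sd Noise sd in normalized units.
#' @param baseline_duration Normalization window, seconds (default 420).
#' @param seed RNG seed.
#' @return Data frame with `time_s` and `ldf` (arbitrary perfusion units).
#' @export
simulate_ldf <- function(cbf_profile, times, attenuation = 0.5,
                         noise_sd = 0.01, baseline_duration = 420, seed = 1) {
  stopifnot(length(cbf_profile) == length(times), attenuation >= 0)
  set.seed(seed)
  base <- mean(cbf_profile[times < baseline_duration])
  rel <- 1 + attenuation * (cbf_profile / base - 1)
  data.frame(time_s = times,
             ldf = 100 * rel + stats::rnorm(length(rel), 0, 100 * noise_sd))
}

#' Cohort specification with study-style generative defaults
#'
#' Describes a two-genotype longitudinal mouse cohort. Per-group endpoint
#' distributions are given as median and quartiles; values are drawn from a
#' normal location-scale family truncated at zero with sd = IQR/1.349, a
#' mouse-level random effect inducing longitudinal correlation `rho`, and a
#' dropout schedule. Defaults reproduce a longitudinal design of 9
#' wild-type and 9 transgenic mice imaged at 3, 6, 9 and 12 months under
#' isoflurane (plus a terminal urethane/alpha-chloralose session), with two
#' transgenic dropouts at 2.5 and 10 months.
#'
#' @param n_wt,n_tg Mice per genotype.
#' @param rho Within-mouse correlation of endpoints across ages.
#' @param dropouts Data frame with `genotype`, `mouse`, `age_months`: the
#'   mouse is absent from sessions at ages >= `age_months`.
#' @param params Data frame with columns `genotype`, `anesthesia`,
#'   `age_months`, `endpoint`, `median`, `q1`, `q3`. Defaults carry
#'   mid-brain CBF (mL/100 g/min), CVR (%) and ATT (ms) values typical of
#'   this design.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_wt = 9, n_tg = 9, rho = 0.5,
                        dropouts = data.frame(
                          genotype = c("TG", "TG"),
                          mouse = c(8L, 9L),
                          age_months = c(2.5, 10)),
                        params = NULL) {
  if (is.null(params)) {
    params <- rbind(
      # isoflurane baseline CBF, mid-brain
      data.frame(genotype = "WT", anesthesia = "isoflurane",
                 age_months = c(3, 6, 9, 12), endpoint = "cbf",
                 median = c(155, 121, 121, 126),
                 q1 = c(143, 112, 112, 84), q3 = c(159, 124, 124, 141)),
      data.frame(genotype = "TG", anesthesia = "isoflurane",
                 age_months = c(3, 6, 9, 12), endpoint = "cbf",
                 median = c(147, 126, 126, 114),
                 q1 = c(133, 103, 103, 103), q3 = c(151, 135, 135, 130)),
      # isoflurane CVR, mid-brain
      data.frame(genotype = "WT", anesthesia = "isoflurane",
                 age_months = c(3, 6, 9, 12), endpoint = "cvr",
                 median = c(13, 31, 31, 26),
                 q1 = c(7, 23, 23, 6), q3 = c(17, 37, 37, 47)),
      data.frame(genotype = "TG", anesthesia = "isoflurane",
                 age_months = c(3, 6, 9, 12), endpoint = "cvr",
                 median = c(13, 30, 30, 30),
                 q1 = c(8, 20, 20, 17), q3 = c(18, 35, 35, 34)),
      # terminal urethane/alpha-chloralose session
      data.frame(genotype = c("WT", "TG"), anesthesia = "ua",
                 age_months = 12.3, endpoint = "cbf",
                 median = c(28, 25), q1 = c(26, 21), q3 = c(30, 40)),
      data.frame(genotype = c("WT", "TG"), anesthesia = "ua",
                 age_months = 12.3, endpoint = "cvr",
                 median = c(233, 265), q1 = c(193, 178), q3 = c(245, 312)),
      # transit times at 12 months, baseline and hypercapnic
      data.frame(genotype = c("WT", "TG"), anesthesia = "isoflurane",
                 age_months = 12, endpoint = "att",
                 median = c(206, 223), q1 = c(186, 202), q3 = c(240, 246)),
      data.frame(genotype = c("WT", "TG"), anesthesia = "isoflurane",
                 age_months = 12, endpoint = "att_co2",
                 median = c(192, 197), q1 = c(189, 187), q3 = c(205, 207))
    )
  }
  stopifnot(n_wt >= 1, n_tg >= 1, rho >= 0, rho < 1,
            all(params$q3 >= params$q1))
  structure(list(n_wt = n_wt, n_tg = n_tg, rho = rho,
                 dropouts = dropouts, params = params),
            class = "cohort_spec")
}

#' Simulate a cohort endpoint table
#'
#' Draws one value per mouse, session and endpoint from the cohort
#' specification: value = median + sd * (sqrt(rho) * z_mouse +
#' sqrt(1-rho) * eps), sd = IQR/1.349, redrawn while negative (truncation
#' at zero). Dropped-out mice are absent from sessions at or after their
#' dropout age.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed.
#' @return Data frame (`mouse_id`, `genotype`, `anesthesia`, `age_months`,
#'   `endpoint`, `value`), one row per mouse x session x endpoint.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  mice <- rbind(
    data.frame(genotype = "WT", mouse = seq_len(spec$n_wt)),
    data.frame(genotype = "TG", mouse = seq_len(spec$n_tg)))
  mice$mouse_id <- paste0(mice$genotype, mice$mouse)
  # mouse-level random effect shared across that mouse's endpoints/ages
  z <- stats::rnorm(nrow(mice))
  rows <- list()
  for (g in seq_len(nrow(spec$params))) {
    p <- spec$params[g, ]
    grp <- mice[mice$genotype == p$genotype, ]
    drop_ages <- spec$dropouts$age_months[
      match(paste0(grp$genotype, grp$mouse),
            paste0(spec$dropouts$genotype, spec$dropouts$mouse))]
    keep <- is.na(drop_ages) | p$age_months < drop_ages
    grp <- grp[keep, , drop = FALSE]
    if (!nrow(grp)) next
    sdv <- (p$q3 - p$q1) / 1.349
    zi <- z[match(grp$mouse_id, mice$mouse_id)]
    val <- vapply(seq_len(nrow(grp)), function(i) {
      repeat {
        v <- p$median + sdv * (sqrt(spec$rho) * zi[i] +
                                 sqrt(1 - spec$rho) * stats::rnorm(1))
        if (v >= 0 || sdv == 0) return(max(v, 0))
      }
    }, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      mouse_id = grp$mouse_id, genotype = p$genotype,
      anesthesia = p$anesthesia, age_months = p$age_months,
      endpoint = p$endpoint, value = val)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
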