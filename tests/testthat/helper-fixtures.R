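# Shared fixtures: default acquisition/tissue parameters and small helpers
# used across the module tests.

acq0 <- acq_params()                     # tau 3000, PLD 300, T1b 2230, lambda 0.9, alpha 0.9
tis0 <- tissue_params(1700, 1000)

# difference signal at the standard readout time tau + PLD
readout_dm <- function(cbf, att = 0, tis = tis0, acq = acq0) {
  gkm_delta_m(perfusion_truth(cbf, att), tis, acq, acq$tau + acq$pld)
}

# true per-sub-bolus signals for a te-pCASL scheme
te_truth_signal <- function(cbf, att, scheme, tis = tis0, acq = acq0) {
  vapply(seq_along(scheme$effective_plds), function(j) {
    a <- acq
    a$tau <- scheme$subbolus_durations[j]
    gkm_delta_m(perfusion_truth(cbf, att), tis, a,
                scheme$subbolus_durations[j] + scheme$effective_plds[j])
  }, numeric(1))
}

# phantom with uniform tissue and a single perfusion truth in all regions,
# for exact end-to-end recovery checks
uniform_phantom <- function(cbf = 120, cvr = 30, att = 200, noise_sd = 0) {
  reg <- list(cbf = cbf, cvr = cvr, att = att,
              t1_tissue = 1700, m0_tissue = 1000)
  phantom_spec(regions = list(cortex = reg, thalamus = reg,
                              midbrain_rest = reg),
               noise_sd = noise_sd)
}

# frame-noise fraction of M0 giving the requested difference-signal SNR
noise_frac_for_snr <- function(snr, cbf = 120, att = 200) {
  readout_dm(cbf, att) / (snr * tis0$m0_tissue)
}
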