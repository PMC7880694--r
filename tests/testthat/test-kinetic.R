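# Kinetic model: quantification equation, forward inflow curve, hypercapnia
# profile.

test_that("quantification formula matches an independent hand evaluation", {
  # deltaM at 1% of M0: evaluate the printed expression literally, in
  # mL/g/ms, then convert
  expected <- 0.9 * 10 * exp(300 / 2230) /
    (2 * 0.9 * 1700 * 1000 * (1 - exp(-3000 / 1700))) * 6.0e6
  expect_equal(quantify_cbf(10, tis0, acq0), expected)
  expect_equal(expected, 24.4, tolerance = 0.01)
  expect_identical(quantify_cbf(0, tis0, acq0), 0)
})

test_that("quantification is linear in deltaM and scales with alpha and M0t", {
  base <- quantify_cbf(10, tis0, acq0)
  expect_equal(quantify_cbf(30, tis0, acq0), 3 * base)
  expect_equal(quantify_cbf(c(10, 20), tis0, acq0), c(base, 2 * base))
  half_alpha <- acq_params(alpha = 0.45)
  expect_equal(quantify_cbf(10, tis0, half_alpha), 2 * base)
  double_m0 <- tissue_params(1700, 2000)
  expect_equal(quantify_cbf(10, double_m0, acq0), base / 2)
})

test_that("quantification rejects bad input and degenerate acquisitions", {
  expect_error(quantify_cbf(NaN, tis0, acq0), "non-finite")
  expect_error(quantify_cbf(Inf, tis0, acq0), "non-finite")
  expect_error(acq_params(tau = -1), "tau")
  expect_error(acq_params(alpha = 1.5), "alpha")
  expect_error(tissue_params(t1_tissue = 0), "t1_tissue")
  # tau so short relative to T1t that the bolus term underflows
  tiny <- acq_params(tau = 1e-12)
  expect_error(quantify_cbf(10, tissue_params(1e6, 1000), tiny), "degenerate")
})

test_that("forward model inverts exactly at zero transit time", {
  for (cbf in c(5, 40, 120, 300)) {
    for (t1t in c(1000, 1400, 1800, 2200)) {
      tis <- tissue_params(t1t, 1000)
      dm <- gkm_delta_m(perfusion_truth(cbf, 0), tis, acq0,
                        acq0$tau + acq0$pld)
      expect_equal(quantify_cbf(dm, tis, acq0), cbf, tolerance = 1e-12)
    }
  }
})

test_that("inflow curve is zero before arrival and for zero flow", {
  tr <- perfusion_truth(120, 400)
  expect_identical(gkm_delta_m(tr, tis0, acq0, c(0, 100, 399.9)),
                   c(0, 0, 0))
  expect_identical(gkm_delta_m(perfusion_truth(0, 0), tis0, acq0,
                               c(0, 500, 5000)), c(0, 0, 0))
  expect_error(gkm_delta_m(tr, tis0, acq0, -5), "t must be")
})

test_that("inflow curve rises monotonically during the bolus", {
  tr <- perfusion_truth(150, 250)
  tt <- seq(250, 3250, by = 10)
  dm <- gkm_delta_m(tr, tis0, acq0, tt)
  # numerical-derivative oracle on the grid
  expect_true(all(diff(dm) >= -1e-12))
  expect_gt(dm[length(dm)], dm[1])
})

test_that("inflow curve is continuous at arrival and bolus end", {
  tr <- perfusion_truth(150, 250)
  peak <- max(gkm_delta_m(tr, tis0, acq0, seq(0, 5000, by = 25)))
  eps <- 1e-6
  for (tb in c(250, 250 + 3000)) {
    jump <- abs(gkm_delta_m(tr, tis0, acq0, tb + eps) -
                  gkm_delta_m(tr, tis0, acq0, max(tb - eps, 0)))
    expect_lt(jump, 1e-9 * peak)
  }
})

test_that("difference signal at readout is transit-time invariant up to PLD", {
  # label decays with the blood T1 throughout transit and wait, so any
  # att <= PLD gives the same readout signal and quantification stays exact
  dm0 <- readout_dm(120, att = 0)
  for (att in c(50, 150, 300)) expect_equal(readout_dm(120, att), dm0)
})

test_that("hypercapnia profile follows the block design", {
  times <- seq(0, 1260, by = 14)
  flat <- hypercapnia_cbf_profile(100, 0, 420, 840, 30, times)
  expect_true(all(flat == 100))
  # step limit: tiny time constant reaches the plateau immediately
  step <- hypercapnia_cbf_profile(100, 30, 420, 840, 1e-9, c(421, 839))
  expect_equal(step, c(130, 130))
  # closed form one time constant after onset
  expect_equal(hypercapnia_cbf_profile(100, 30, 420, 840, 30, 450),
               100 * (1 + 0.30 * (1 - exp(-1))))
  expect_error(hypercapnia_cbf_profile(100, 30, 840, 420, 30, times), "t_on")
  expect_error(hypercapnia_cbf_profile(100, 30, 420, 840, 0, times),
               "tau_response")
})

test_that("acquisition sidecars round-trip through JSON and YAML", {
  acq <- acq_params(alpha = 0.85)
  for (ext in c("json", "yaml")) {
    p <- file.path(tempdir(), paste0("sidecar.", ext))
    write_sidecar(acq, 180, 1260, 420, 840, p)
    got <- read_sidecar(p)
    expect_equal(got$acq$alpha, 0.85)
    expect_equal(got$acq$tau, 3000)
    expect_equal(got$n_dynamics, 180L)
    expect_equal(got$co2_off_s, 840)
  }
  bad <- file.path(tempdir(), "bad.json")
  jsonlite::write_json(list(tau_ms = 3000), bad, auto_unbox = TRUE)
  expect_error(read_sidecar(bad), "missing keys")
})
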