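# Synthetic-data generators: determinism, truth recovery, cohort structure.

test_that("generators are deterministic under a fixed seed", {
  ph <- phantom_spec(noise_sd = 0.01)
  r1 <- simulate_pcasl_run(ph, seed = 11)
  r2 <- simulate_pcasl_run(ph, seed = 11)
  expect_identical(r1$volumes, r2$volumes)
  expect_false(identical(simulate_pcasl_run(ph, seed = 12)$volumes,
                         r1$volumes))
  expect_identical(simulate_ir(ph, seed = 3), simulate_ir(ph, seed = 3))
  expect_identical(simulate_te_pcasl(ph, seed = 4),
                   simulate_te_pcasl(ph, seed = 4))
  expect_identical(simulate_cohort(seed = 5), simulate_cohort(seed = 5))
  prof <- rep(100, 90)
  expect_identical(simulate_ldf(prof, (0:89) * 14, seed = 6),
                   simulate_ldf(prof, (0:89) * 14, seed = 6))
})

test_that("a noiseless run is recovered exactly by the pipeline", {
  ph <- uniform_phantom(cbf = 120, cvr = 30, att = 200, noise_sd = 0)
  run <- simulate_pcasl_run(ph, acq0, seed = 1)
  res <- quantify_run(run, 1700, 1000, acq0,
                      phantom_masks(ph)["midbrain"])
  expect_equal(res$baseline_cbf[["midbrain"]], 120, tolerance = 1e-6)
  expect_equal(res$cvr[["midbrain"]], 30, tolerance = 0.01)
})

test_that("recovery error decreases with SNR", {
  errs <- vapply(c(2, 10, 50), function(snr) {
    ph <- uniform_phantom(cbf = 120, cvr = 30,
                          noise_sd = noise_frac_for_snr(snr))
    mean(vapply(1:3, function(s) {
      run <- simulate_pcasl_run(ph, acq0, seed = 100 + s)
      res <- quantify_run(run, 1700, 1000, acq0,
                          phantom_masks(ph)["midbrain"])
      abs(res$baseline_cbf[["midbrain"]] - 120)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("phantom regions are disjoint and masks match the labels", {
  ph <- phantom_spec()
  overlap <- ph$masks$cortex & ph$masks$thalamus |
    ph$masks$cortex & ph$masks$midbrain_rest |
    ph$masks$thalamus & ph$masks$midbrain_rest
  expect_false(any(overlap))
  expect_true(all(vapply(ph$masks, sum, numeric(1)) > 0))
  union <- phantom_masks(ph)$midbrain
  expect_equal(sum(union), sum(ph$labels > 0))
})

test_that("noiseless te-pCASL simulation yields exact ATT estimates", {
  ph <- uniform_phantom(cbf = 150, cvr = 30, att = 220, noise_sd = 0)
  sim <- simulate_te_pcasl(ph, seed = 1)
  sch <- attr(sim, "scheme")
  for (reg in names(sim)) {
    dec <- te_decode(sim[[reg]]$encoded, sch)
    fit <- estimate_att(dec, tis0, acq0)
    expect_equal(fit$att, sim[[reg]]$truth$att, tolerance = 1)
  }
  # hypercapnic state: shorter transit time recovered as shorter estimate
  sim_hc <- simulate_te_pcasl(ph, state = "hypercapnia",
                              att_shortening = 30, seed = 1)
  fit_b <- estimate_att(te_decode(sim[["cortex"]]$encoded, sch), tis0, acq0)
  fit_h <- estimate_att(te_decode(sim_hc[["cortex"]]$encoded, sch), tis0, acq0)
  expect_lt(fit_h$att, fit_b$att)
  expect_equal(fit_b$att - fit_h$att, 30, tolerance = 2)
})

test_that("simulated IR series recover the phantom tissue parameters", {
  ph <- uniform_phantom(noise_sd = 0)
  ti <- c(50, 150, 300, 600, 1200, 2400, 4800, 8000)
  arr <- simulate_ir(ph, ti, seed = 1)
  v <- which(ph$masks$cortex, arr.ind = TRUE)[1, ]
  fit <- fit_inversion_recovery(arr[v[1], v[2], v[3], ], ti)
  expect_equal(fit$t1_tissue, 1700, tolerance = 1e-3)
  expect_equal(fit$m0_tissue, 1000, tolerance = 1e-3)
})

test_that("cohort tables honour group sizes and the dropout schedule", {
  tab <- simulate_cohort(seed = 42)
  n_at <- function(a, g) length(unique(
    tab$mouse_id[tab$age_months == a & tab$genotype == g &
                   tab$endpoint == "cbf"]))
  expect_equal(n_at(3, "WT"), 9)
  expect_equal(n_at(3, "TG"), 8)   # first dropout before the first session
  expect_equal(n_at(12, "WT"), 9)
  expect_equal(n_at(12, "TG"), 7)  # second dropout at 10 months
  expect_true(all(tab$value >= 0))
  # one value per mouse x session x endpoint
  expect_false(any(duplicated(
    tab[, c("mouse_id", "age_months", "anesthesia", "endpoint")])))
})

test_that("zero-spread cohort specs give identical mice", {
  sp <- cohort_spec()
  sp$params$q1 <- sp$params$median
  sp$params$q3 <- sp$params$median
  tab <- simulate_cohort(sp, seed = 1)
  sub <- tab[tab$endpoint == "cbf" & tab$age_months == 3 &
               tab$genotype == "WT", ]
  expect_true(all(sub$value == sub$value[1]))
})

test_that("large cohorts reproduce the generative medians", {
  sp <- cohort_spec(n_wt = 5000, n_tg = 5000,
                    dropouts = data.frame(genotype = character(),
                                          mouse = integer(),
                                          age_months = numeric()))
  sp$params <- sp$params[sp$params$age_months == 3 &
                           sp$params$endpoint == "cbf", ]
  tab <- simulate_cohort(sp, seed = 8)
  for (g in c("WT", "TG")) {
    target <- sp$params$median[sp$params$genotype == g]
    got <- median(tab$value[tab$genotype == g])
    expect_equal(got, target, tolerance = 0.01)
  }
})

test_that("LDF traces attenuate the relative CBF response", {
  times <- (0:89) * 14
  prof <- hypercapnia_cbf_profile(100, 30, 420, 840, 1e-9, times)
  full <- simulate_ldf(prof, times, attenuation = 1, noise_sd = 0)
  norm_full <- ldf_normalize(full$ldf, times)
  expect_equal(mean(norm_full[times > 560 & times < 840]), 1.30,
               tolerance = 1e-3)
  half <- simulate_ldf(prof, times, attenuation = 0.5, noise_sd = 0)
  norm_half <- ldf_normalize(half$ldf, times)
  expect_equal(mean(norm_half[times > 560 & times < 840]), 1.15,
               tolerance = 1e-3)
})
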