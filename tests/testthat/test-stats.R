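# Nonparametric cohort statistics under SPSS conventions.

test_that("exact Mann-Whitney null distribution matches full enumeration", {
  # brute-force oracle: all C(7,3) assignments of ranks 1..7 to sample 1
  n1 <- 3; n2 <- 4
  combos <- combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(s) sum(s) - n1 * (n1 + 1) / 2)
  for (u_obs in 0:(n1 * n2)) {
    lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
    p_oracle <- min(1, 2 * min(lo, hi))
    # construct untied samples realising U = u_obs
    ranks1 <- 1:n1
    rem <- u_obs
    for (i in n1:1) {
      inc <- min(rem, n2); ranks1[i] <- ranks1[i] + inc; rem <- rem - inc
    }
    x <- ranks1; y <- setdiff(1:(n1 + n2), ranks1)
    tst <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(unname(tst$statistic), u_obs)
    expect_equal(tst$p, p_oracle)
  }
})

test_that("Mann-Whitney examples and edge cases behave", {
  tst <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(tst$statistic), 0)
  expect_equal(tst$p, 2 / 6)
  # identical samples: U = n^2/2 and p = 1
  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(tied$statistic), 9 / 2)
  expect_equal(tied$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
  expect_error(mann_whitney_u(c(1, NA), 1:3), "missing")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3, 4), mode = "exact"),
               "ties")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9, 0.5)
    ours <- mann_whitney_u(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    asym <- mann_whitney_u(x, y, mode = "asymptotic")
    ref_a <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(asym$p, ref_a$p.value, tolerance = 1e-9)
  }
})

test_that("signed-rank test follows the zero-drop, tie-corrected convention", {
  # nine distinct decreases: W+ = 0
  tst <- wilcoxon_signed_rank((1:9) * 10, (1:9) * 10 - (1:9))
  expect_equal(unname(tst$statistic), 0)
  expect_equal(tst$z, -22.5 / sqrt(9 * 10 * 19 / 24), tolerance = 1e-12)
  # zero differences are dropped before ranking
  pre <- c(5, 5, (1:9) * 10); post <- c(5, 5, (1:9) * 10 - (1:9))
  tst2 <- wilcoxon_signed_rank(pre, post)
  expect_equal(tst2$n, 9)
  expect_equal(tst2$z, tst$z)
  # perfectly antisymmetric differences: W+ = W-, Z = 0, p = 1
  d <- c(-4, -2, 2, 4)
  tst3 <- wilcoxon_signed_rank(rep(0, 4), d)
  expect_equal(tst3$z, 0)
  expect_equal(tst3$p, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "paired")
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "non-zero")
})

test_that("signed-rank Z is antisymmetric and matches the reference", {
  set.seed(31)
  for (i in 1:10) {
    pre <- rnorm(9); post <- pre + rnorm(9, -0.5)
    up <- wilcoxon_signed_rank(pre, post)
    dn <- wilcoxon_signed_rank(post, pre)
    expect_equal(up$z, -dn$z, tolerance = 1e-12)
    ref <- wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                       correct = FALSE)
    expect_equal(unname(up$statistic), unname(ref$statistic))
    expect_equal(up$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Friedman statistic matches hand ranks and the reference", {
  # every subject identical across conditions: all within-row ties, chi2 = 0
  same <- matrix(rep(1:4, 3), 4, 3)
  expect_equal(unname(friedman(same)$statistic), 0)
  inc <- matrix(c(1, 2, 3, 2, 4, 6, 10, 20, 30), 3, 3, byrow = TRUE)
  tst <- friedman(inc)
  expect_equal(unname(tst$statistic), 6)
  expect_equal(tst$dof, 2)
  expect_equal(tst$p, pchisq(6, 2, lower.tail = FALSE))
  set.seed(41)
  m <- matrix(rnorm(36), 9, 4)
  ref <- friedman.test(m)
  expect_equal(unname(friedman(m)$statistic), unname(ref$statistic),
               tolerance = 1e-9)
  expect_equal(friedman(m)$p, ref$p.value, tolerance = 1e-9)
  # permuting condition labels leaves the statistic unchanged
  expect_equal(unname(friedman(m[, c(3, 1, 4, 2)])$statistic),
               unname(friedman(m)$statistic))
  # rows with missing sessions are dropped (complete-case)
  m_na <- rbind(m, c(NA, 1, 2, 3))
  expect_equal(friedman(m_na)$n, 9)
})

test_that("Bonferroni post hocs use the alpha/m cut-off", {
  dec <- bonferroni_posthoc(c(0.008, 0.036, 0.5), m = 3)
  expect_equal(dec$cutoff, rep(0.05 / 3, 3), tolerance = 1e-12)
  expect_equal(dec$significant, c(TRUE, FALSE, FALSE))
  expect_true(bonferroni_posthoc(0.04, m = 1)$significant)
  expect_equal(round(bonferroni_posthoc(0.02, m = 3)$cutoff, 3), 0.017)
})

test_that("median/IQR summaries use Tukey hinges", {
  expect_equal(median_iqr(1:9), c(median = 5, q1 = 3, q3 = 7))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  set.seed(51)
  for (n in c(4, 7, 10, 25)) {
    x <- rnorm(n)
    s <- median_iqr(x)
    fv <- fivenum(x)  # Tukey five-number summary as oracle
    expect_equal(unname(s[c("q1", "median", "q3")]), fv[2:4])
  }
})

test_that("the cohort battery runs the study's analysis plan", {
  tab <- simulate_cohort(seed = 7)
  res <- cohort_stats(tab)
  expect_setequal(names(res),
                  c("genotype", "age", "posthoc", "anesthesia", "summaries"))
  expect_equal(nrow(res$genotype), 2 * 4)  # 2 endpoints x 4 ages
  expect_true(all(res$genotype$p >= 0 & res$genotype$p <= 1))
  expect_equal(res$genotype$n_wt, rep(9, 8))
  expect_equal(res$age$n[res$age$genotype == "TG"], c(7, 7))
  expect_equal(unique(res$posthoc$cutoff), 0.05 / 3)
  # anesthesia contrast pairs the 12-month isoflurane and terminal sessions
  # (9 complete WT pairs, 7 TG after the dropouts)
  expect_equal(res$anesthesia$n,
               ifelse(res$anesthesia$genotype == "WT", 9, 7))
  expect_true(all(is.finite(res$anesthesia$z)))
  # the terminal-session CBF collapse is large and consistently detected
  cbf_an <- res$anesthesia[res$anesthesia$endpoint == "cbf", ]
  expect_true(all(cbf_an$p < 0.05))
})
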