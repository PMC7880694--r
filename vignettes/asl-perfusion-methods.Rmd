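---
title: "Models and methods: pCASL perfusion, reactivity, transit time and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pCASL perfusion, reactivity, transit time and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslperf)
```

## Scope

`aslperf` implements a complete analysis chain for pseudo-continuous
arterial spin labeling (pCASL) MRI of the mouse brain: absolute cerebral
blood flow (CBF) quantification with the general kinetic model,
cerebrovascular reactivity (CVR) from a hypercapnia block design, arterial
transit time (ATT) from Hadamard time-encoded pCASL, tissue T1/M0 from
inversion recovery, laser Doppler flowmetry (LDF) normalization, and the
nonparametric statistics appropriate for small longitudinal rodent cohorts.
A synthetic-data layer generates every input with known ground truth, so
each stage of the chain is testable end to end.

## CBF quantification

The perfusion-weighted signal is the control-minus-label difference ΔM of
each frame pair. `quantify_cbf()` converts it to absolute flow with the
single-compartment kinetic model:

$$ \mathrm{CBF} \;=\; \frac{\lambda\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
   {2\,\alpha\,T_{1t}\,M_{0t}\,\bigl(1 - e^{-\tau/T_{1t}}\bigr)} $$

evaluated in mL/g/ms and multiplied by $6\times10^6$ to give the
conventional mL/100 g/min. Parameters, with defaults for a 7 T mouse
protocol:

| parameter | meaning | default | unit |
|---|---|---|---|
| τ | labeling duration | 3000 | ms |
| PLD | post-labeling delay | 300 | ms |
| $T_{1b}$ | blood longitudinal relaxation | 2230 | ms |
| λ | blood–brain partition coefficient | 0.9 | mL/g |
| α | labeling efficiency | 0.9 | – |
| $T_{1t}$, $M_{0t}$ | tissue relaxation / magnetization | from IR fit (1700 ms, a.u.) | ms, a.u. |

α is a configuration input: in practice it is measured per animal with a
flow-compensated acquisition at the carotids, which is outside this
package's scope. The default 0.9 is a typical pCASL train efficiency and
every function accepts an override. The default $T_{1t}$ of 1700 ms is
representative of mouse brain tissue at 7 T and is only used by the
simulators when no inversion-recovery fit is supplied.

### Forward model and its conventions

`gkm_delta_m()` is the forward counterpart used by the simulators and the
ATT fit. It is piecewise in time since label onset: zero before the label
arrives (t < ATT), accumulation with the tissue T1 during bolus delivery,
and decay afterwards. The label magnetization decays with the *blood* T1
during transit and during the post-bolus wait. This convention was chosen
deliberately so that the quantification equation above is the exact
algebraic inverse of the forward model at ATT = 0 — the package's
round-trip tests exploit this to machine precision.

Two consequences are worth knowing. First, for any ATT ≤ PLD the readout
signal of a fully delivered bolus is proportional to
$e^{-(t-\tau)/T_{1b}}$ and therefore *independent* of ATT: quantification
stays exactly unbiased for transit times up to the PLD, which covers the
mouse brain (ATT ≈ 200 ms, PLD = 300 ms). Second, the same invariance
limits ATT identifiability in the time-encoded fit (see below). A model in
which in-tissue label decays with the tissue T1 after bolus arrival would
break the exact inversion property of the printed equation; we prioritized
the inversion.

## The hypercapnia pipeline

A run is 180 frames (alternating label/control) over 21 min with 7.5% CO₂
administered between minutes 7 and 14. Processing follows fixed
definitions:

* **Pairwise subtraction** (`pairwise_delta_m()`): 180 frames → 90
  difference dynamics, 14 s apart.
* **Voxelwise quantification** (`cbf_series()`), with per-voxel T1/M0 maps
  when an IR scan is available.
* **ROI profiles** (`roi_profile()`): mean over a mask per dynamic; masked
  or flagged voxels are excluded, never zero-filled.
* **Sliding-window filter** (`sliding_window_filter()`): centred moving
  average of three dynamics (seven for the craniotomy cortical ROI use
  case); edges use the shrunken window.
* **Baseline CBF** (`baseline_cbf()`): mean of the last 20 difference
  dynamics that start before CO₂ onset. With 90 dynamics and onset at
  420 s those are dynamics 11–30.
* **CVR** (`cvr()`): percent change of the plateau (last 20 dynamics inside
  the CO₂ window) over baseline, $100\,(\text{post}/\text{pre}-1)$.
  Reported reactivity values of order 10–30% under isoflurane and >200%
  under urethane/α-chloralose are only meaningful on the percent-change
  scale, which is why the package does not report the raw ratio.

The window length "20 repetitions" is counted in difference dynamics (the
unit of a CBF time profile), not raw frames. Frame alignment is exposed as
`align_frames()`, an identity on simulated (motion-free) data, so that a
registration step can be slotted in for real acquisitions without changing
the pipeline.

LDF traces are filtered with the same three-point window and normalized to
the mean signal of the first 7 minutes (`ldf_normalize()`), making ASL and
LDF reactivities directly comparable as dimensionless plateaus.

## Time-encoded pCASL and the ATT fit

`build_scheme()` constructs a Sylvester Hadamard matrix of order
$n_{\text{sub}}+1$ and drops the all-ones column; +1 entries label a
sub-bolus, −1 leave it as control, and each sub-bolus is labeled in half
the encodes. The default is Hadamard-8: seven sub-boli of 250 ms and a
50 ms readout gap, giving effective post-labeling delays of 50–1550 ms —
bracketing the expected mouse ATT of ~200 ms. `te_decode()` recovers the
per-sub-bolus ΔM by linear least squares with an intercept (the static
tissue signal); for a complete scheme this is the exact inverse of the
encoding and it degrades gracefully if encodes are dropped, as long as the
design stays full rank.

`estimate_att()` fits (CBF, ATT) to the decoded inflow curve. The model is
linear in CBF, so for each candidate ATT the optimal CBF is closed-form;
ATT is found on a 10 ms grid over [0, max PLD + sub-bolus duration]
followed by bounded golden-section refinement, with exact ties resolved
toward the smaller ATT. Non-informative data (an all-zero decoded series)
return `NA` with `converged = FALSE` rather than an arbitrary number.

**Identifiability limit.** Because a fully delivered sub-bolus is
ATT-invariant under the forward convention above, transit times at or
below the shortest effective PLD (50 ms in the default scheme) produce
identical data: noiseless ATT = 0 and ATT = 50 ms cannot be distinguished,
and Monte-Carlo recovery at exactly 50 ms is biased low by the
ties-toward-smaller rule. Recovery is unbiased to a few ms for ATT from
100 to 400 ms at difference-signal SNR 20 (the package's acceptance suite
measures this). For applications expecting very short transit times the
scheme's readout gap should be shortened.

## Inversion-recovery relaxometry

`fit_inversion_recovery()` fits $S(TI) = \lvert M_0 (1 - 2\beta
e^{-TI/T_1})\rvert$ with inversion factor β ∈ (0.5, 1]. Magnitude images
lose the sign of the recovering magnetization, so every polarity
restoration point is tried: the first k signals are negated and the signed
model is fitted, the restoration with the lowest residual winning. For
fixed T1 the model is linear in $(M_0,\,M_0\beta)$, so only T1 is optimized
numerically — Brent's method on log T1, initialized at
$TI_{\min\text{signal}}/\ln 2$, followed by two parabolic polish steps
that push noiseless fits to machine-level residuals. Fits with T1 outside
(100, 5000) ms or β outside (0.5, 1] are flagged rather than silently
returned. Per-voxel maps (`fit_ir_map()`) and per-ROI fits are both
available; per-voxel is the default in the quantification pipeline since
it makes no homogeneity assumption.

## Synthetic data

The generators define the study conditions under which the package is
validated:

* **Phantom** (`phantom_spec()`): a 16×16×3 grid (0.225×0.225×1.5 mm
  voxels) with three disjoint regions on a brain-like oval — dorsal
  cortical band, central thalamic blob, remaining mid-brain tissue — each
  carrying its own CBF, CVR, ATT, T1t, M0t. Defaults (cortex 155
  mL/100 g/min and CVR 30%, deep tissue ~100–120 and 10–15%, ATT ~200 ms)
  reflect an adult mouse under isoflurane with a cortically dominant
  hypercapnic response.
* **pCASL runs** (`simulate_pcasl_run()`): control frames $M_{0t}+\epsilon$,
  label frames $M_{0t}-\Delta M(t)+\epsilon$, with regional CBF following a
  mono-exponential block design (`hypercapnia_cbf_profile()`; response time
  constant 30 s by default, 120 s being more representative of the slower
  urethane/α-chloralose response). Noise is additive Gaussian on frames —
  at the difference-signal SNR of interest (≥20) Rician bias is negligible,
  but a Rician option exists (`noise_model = "rician"`).
* **IR and te-pCASL series** (`simulate_ir()`, `simulate_te_pcasl()`),
  sharing the same phantom truth; the hypercapnic te-pCASL state raises
  CBF by the regional CVR and shortens ATT by a configurable 20 ms.
* **Cohorts** (`cohort_spec()`, `simulate_cohort()`): two genotypes × 9
  mice imaged at 3, 6, 9 and 12 months plus a terminal session, endpoint
  distributions specified as median/quartiles, values drawn from a normal
  family truncated at zero with sd = IQR/1.349, a mouse-level random
  effect giving within-mouse correlation ρ = 0.5 across ages (the true
  longitudinal correlation is unknown; 0.5 is a deliberate middle choice
  and configurable), and two transgenic dropouts at 2.5 and 10 months so
  that 9 vs 7 animals remain at 12 months. Where the generative medians for
  9 months are not separately specified they carry the 6-month values
  forward, matching a stable post-6-month plateau.
* **LDF** (`simulate_ldf()`): relative perfusion with the hypercapnic
  response attenuated by a factor 0.5 by default, reflecting surface LDF
  reading roughly half the ASL reactivity.

All generators are deterministic under a seed. What the phantom does *not*
emulate: anatomically realistic geometry, motion, partial-volume mixtures
at region borders, BOLD contamination of the control images, or
physiological CO₂ feedback. Passing recovery tests on this phantom
therefore validates the processing arithmetic and estimator statistics,
not robustness to those real-data effects.

## Cohort statistics

The battery (`cohort_stats()`) mirrors how such small longitudinal cohorts
are analysed in SPSS, and the individual tests are exposed directly:

* `mann_whitney_u()` — genotype contrasts. Exact two-sided p by full
  enumeration of the U null (dynamic programming) when min(n) ≤ 10 and no
  ties; otherwise a normal approximation with tie-corrected variance *and
  a continuity correction*. The correction matters: without it the
  asymptotic p can differ from the exact enumeration by up to ~0.04 at
  n = 9 vs 9, with it by less than 0.01.
* `wilcoxon_signed_rank()` — paired anesthesia and CO₂ contrasts. SPSS
  conventions exactly: zero differences dropped, midranks of |d|,
  tie-corrected variance, *no* continuity correction, p from the normal
  tail. These conventions are the only ones that reproduce small-sample Z
  statistics such as −2.67 for nine uniformly decreasing pairs; hence the
  deliberate asymmetry with the Mann–Whitney choice above.
* `friedman()` — repeated-measures age effect with tie-corrected χ²
  (k − 1 degrees of freedom), complete-case across sessions as appropriate
  for a cohort with dropouts. Tie correction is on by default; without
  ties it reduces to the classical statistic.
* `bonferroni_posthoc()` — consecutive-age contrasts only, so four ages
  cost m = 3 comparisons and the family-wise cut-off is 0.05/3 ≈ 0.017.
* `median_iqr()` — Tukey hinges, matching the median (Q1–Q3) display
  convention of SPSS summaries (`fivenum()` agrees and serves as the test
  oracle).

A note on design power: with the planning assumptions used for such
studies (30-point group difference, sd 12, n = 4 per group) the *exact*
Mann–Whitney cannot reach 80% power at α = 0.05 two-sided — its smallest
achievable p is 2/70 ≈ 0.029, so it rejects only on complete separation of
the groups, an event of probability ≈ 0.68 under those assumptions. The
80% figure corresponds to the uncorrected normal approximation. The test
suite asserts the sharp characterization (rejection ≡ separation) rather
than pretending the exact test meets the planning figure.

## Numerical choices and problem sizes

Degenerate inputs are rejected loudly: odd frame counts, even filter
windows, empty masks, zero baselines (CVR undefined → `NA` with a
warning), rank-deficient encoding schemes, non-finite ΔM. The Monte-Carlo
problem sizes in the test and acceptance suites — 40 replicates per
transit time, 500 inversion-recovery replicates, 10⁴ null simulations for
the type-I error, 20 simulated cohorts — were chosen so each estimate's
Monte-Carlo error is comfortably below the tolerance it is checked
against while the whole suite stays quick to run.

## Limitations

Single-compartment kinetics only (no dispersion, outflow, or
multi-compartment exchange); no partial-volume correction; no deformable
registration (masks are assumed aligned); Bruker raw data must be
converted to NIfTI upstream; the G*Power-style sample-size computation is
discussed above but deliberately not implemented as a tested operation,
since its Mann–Whitney efficiency variant is ambiguous.
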