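Package: aslperf
Title: Arterial Spin Labeling Perfusion Quantification for Mouse Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of cerebral blood flow from pseudo-continuous
    arterial spin labeling (pCASL) MRI using Buxton's general kinetic model,
    cerebrovascular reactivity from hypercapnia block designs, arterial
    transit time from Hadamard time-encoded pCASL, and tissue T1/M0 from
    inversion-recovery series. Includes a synthetic-data generator that
    emulates longitudinal mouse cohort acquisitions with known ground truth,
    and the nonparametric cohort statistics used for such studies (exact
    Mann-Whitney U, SPSS-convention Wilcoxon signed-rank, tie-corrected
    Friedman, Bonferroni-corrected post hocs, Tukey-hinge median/IQR).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
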