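Package: uterodyn
Title: Quantitative Analysis of Dynamic Utero-Placental MRI
Version: 0.1.0
Authors@R:
    person("Placental", "Imaging Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify utero-placental dynamics from dynamic
    (time-resolved, multislice) R2*-weighted MRI. Computes compartment
    volumes, surface areas and placental sphericity from anisotropic,
    gapped label volumes; assembles smoothed time courses including the
    change in the effective transverse relaxation rate (delta-R2*);
    detects contraction events against interpolated rest baselines and
    extracts half-maximum durations and peak feature changes; screens
    sessions for maternal and fetal motion; classifies events as
    placental or uterine with a volume-gate plus sphericity rule; and
    summarises cohorts with Mann-Whitney U comparisons under Bonferroni
    correction. A parametric utero-placental phantom generator produces
    synthetic dynamic sessions with closed-form ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
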