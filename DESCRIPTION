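Package: husphen
Title: High-Frequency Ultrasound and Metabolic Phenotyping of Diet-Induced Obesity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for preclinical high-frequency ultrasound and
    metabolic phenotyping of diet-induced obesity in mice. Computes
    echocardiographic derived indices (Teichholz volumes, ejection fraction,
    fractional shortening, corrected left-ventricular mass, relative wall
    thickness) with allometric body-weight normalization; parametric liver
    B-mode analysis (hepatic-renal and hepatic-portal echogenicity ratios,
    gray-level histogram heterogeneity and anisotropy, portal vein diameter);
    renal Doppler indices (resistive and pulsatility index from pulsed-wave
    velocity traces); metabolic indices (HOMA-IR, food efficiency ratio,
    caloric intake, hepatomegaly); ordinal ultrasound and histology scoring
    (NAFLD activity score, glomerular grading); and the cohort statistics
    layer (exact Mann-Whitney, repeated-measures mixed two-way ANOVA with
    Greenhouse-Geisser correction and Sidak post hoc contrasts, a priori
    sample size). Ships seeded generators for synthetic cohorts, speckle
    phantoms, and arterial velocity waveforms so the full pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    pracma,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
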