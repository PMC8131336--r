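Package: lsvar
Title: Liver Segmental Volume and Attenuation Ratio Analysis for CT
    Fibrosis Scoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes CT-derived liver fibrosis scores -- the liver
    segmental volume ratio (LSVR) between Couinaud segments I-III and
    IV-VIII, the ordinal liver vein to cava attenuation score (LVCA) and
    their composite LSVAR = LSVR * LVCA -- from per-patient measurement
    tables or from labeled voxel phantoms, and evaluates their diagnostic
    performance against an MR-elastography liver-stiffness reference with
    ROC/Youden cutoff analysis, DeLong confidence intervals,
    Mann-Whitney and Fisher group comparisons, and one-way intraclass
    correlation.  Ships a seeded synthetic cohort generator and a CT-like
    labeled phantom generator so the full measurement and evaluation
    chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
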