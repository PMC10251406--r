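Package: matSIP
Title: Isotope Tracer Quantification for Diel Microbial Mat Labeling Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stable-isotope (13C) tracer incorporation in stratified
    phototrophic microbial mats over a diel cycle. Implements delta-notation
    isotope arithmetic against the VPDB standard, two-point calibration,
    a two-end-member atom-fraction mixing model for percent carbon replacement,
    laser-ablation IRMS depth-profile normalization and photic/aphotic
    partitioning by trapezoidal quadrature, acid-wash three-pool mass balance,
    mass-isotopomer-distribution extraction with binomial natural-abundance
    correction and three-level labeling calls, SIPPER-score peptide filtering
    with taxon and KEGG-pathway aggregation, and a synthetic diel-mat data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
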