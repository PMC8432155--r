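Package: polyQscreen
Title: High-Content Quantification of Polyglutamine Inclusions and
    Mitochondrial Function
Version: 0.1.0
Authors@R:
    person("ReNcell", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for a human neural-stem-cell
    model of polyglutamine (CAG-repeat) disease. Segments nuclei from
    high-content fluorescence fields (median filter, batch Otsu threshold,
    distance-transform watershed), calls intra- and extra-nuclear
    huntingtin inclusion bodies with prominence-based maxima detection,
    and computes the full set of per-well inclusion metrics. Also derives
    Mito Stress Test respiratory parameters from oxygen-consumption-rate
    traces, converts spectrophotometric absorbance kinetics to
    electron-transport-chain enzyme activities, and classifies
    mitochondrial volumes into size categories. A synthetic-data
    generator provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
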