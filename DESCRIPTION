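Package: hemifc
Title: Interhemispheric Functional Connectivity Asymmetry Analysis
Version: 0.1.0
Authors@R:
    person("hemifc", "developers", email = "hemifc@example.org", role = c("aut", "cre"))
Description: Tools for analysing hemispheric asymmetry of resting-state
    functional connectivity from parcellated ROI time series. Builds
    subject-level ROI-to-ROI Pearson correlation networks with Fisher
    z-transformation, aggregates per-ROI right- and left-hemisphere
    connectivity (rFC, lFC) above a correlation threshold, computes the
    laterality asymmetry index AI = 100*(rFC-lFC)/((rFC+lFC)/2), and runs
    the full group-testing scheme (edge-wise two-sample contrasts with
    seed-level FDR, within-group paired-t lateralization, between-group
    ANOVA with Bonferroni post hocs, clinical correlations, demographic
    tests). Includes a synthetic multi-subject BOLD-like cohort simulator
    with controllable covariance structure, homotopic coupling, group edge
    effects and per-ROI asymmetry targets, so every stage of the pipeline
    is testable without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
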