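Package: cvrmir
Title: Cerebrovascular Reactivity Mapping, Exosomal miRNA Quantification,
    and Mediation Analysis for Hypertensive Cognitive Impairment Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for studies linking serum exosomal
    microRNA levels, resting-state BOLD-derived cerebrovascular reactivity
    (CVR), and cognitive performance in hypertensive cohorts. Provides
    relative CVR mapping from band-limited (0.02-0.04 Hz) resting-state BOLD
    signal via a global-reference general linear model; qPCR 2^-deltaCt
    miRNA quantification with spike-in normalization and a screen/validate
    biomarker workflow; education-adjusted cognitive impairment
    classification and domain composite Z-scoring; covariate-adjusted group
    statistics (ANOVA, chi-square, ANCOVA with post-hoc contrasts, partial
    correlation); voxel-wise ANCOVA with permutation cluster-extent
    inference; and covariate-adjusted bootstrap mediation analysis. A
    synthetic-data module generates cohorts, 4D BOLD series and Ct panels
    with known ground truth so every stage is testable without any download.
    Includes minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
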