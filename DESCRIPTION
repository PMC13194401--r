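Package: organoidhci
Title: High-Content Imaging Quantification for 3D Organoid-Immune Co-Culture Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for high-content imaging of 3D
    organoid-immune cell co-cultures and ex vivo patient tissue screening
    plates. Segments nuclei, actin-defined multicellular objects and
    tracker-labeled immune cells in multi-channel confocal z-stacks, computes
    per-object morphometry (volume, equivalent diameter, nucleus count) and
    per-well readouts (tumoroid count, cumulative volume, single-cell count,
    immune infiltration), applies well- and plate-level quality-control gates,
    normalizes readouts as percent of control, categorizes drug responses, and
    runs ANOVA with Tukey or Dunnett post-hoc comparisons. Includes a synthetic
    plate generator that renders 3D wells with exact ground truth so the whole
    pipeline is testable without patient material.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    multcomp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
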