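Package: mixscreen
Title: Subpopulation-Resolved Drug Screening of Mixed Tumor Cultures by
    Two-Channel High-Content Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies drug response of cancer-cell subpopulations growing in
    mixed cultures (cancer cells, stromal fibroblasts, irradiated feeder
    layers) from two-channel immunofluorescence well images: nuclear (Hoechst)
    segmentation, cytokeratin-8/18 marker scoring of each nucleus, per-well
    subpopulation counts, growth-plate endpoint logic, four-parameter logistic
    dose-response fitting with IC50 extraction and fold-ratio comparison, and
    exact contingency statistics for culture-establishment cohorts. Includes a
    ground-truthed synthetic plate generator (population dynamics under
    Hill-type drug effect, cell placement and morphology, two-channel image
    rendering) so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    Matrix,
    tiff,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, HighContentScreening, Software
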