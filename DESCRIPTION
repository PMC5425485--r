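Package: edgeFC
Title: Whole-Brain Edge-Wise Functional Connectivity Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Edge-wise group analysis of resting-state functional
    connectivity over a 116-region whole-brain parcellation. Provides
    region-mean time-series extraction from labelled 4-D images,
    time-series denoising (nuisance regression and ideal band-pass
    filtering) with head-motion quality control, subject-level
    Pearson/Fisher-z connectivity matrices, a dual-criterion altered-edge
    selection combining per-group one-sample tests under
    Benjamini-Hochberg false discovery rate control with a between-group
    test calibrated by a within-control split-permutation null, edge
    direction classification, and correlation of edge strength with
    behavioral scores. Includes a synthetic multi-subject BOLD cohort
    generator with block-structured covariance, injected group-difference
    edges, and score-edge couplings, so every stage of the pipeline is
    testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
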