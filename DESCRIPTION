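Package: phenoconn
Title: Smartphone Passive Sensing and Seed-Based Brain Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking passive smartphone sensing features to
    seed-based resting-state functional connectivity. Implements daily
    screen-time (unlock duration) and circadian-similarity feature
    extraction from phone event streams, PHQ-2/4/8 depression survey
    scoring, a motion-scrubbing denoising stream for BOLD runs (framewise
    displacement censoring, Volterra-expanded nuisance regression,
    Lomb-Scargle spectral interpolation of censored frames, band-pass
    filtering), subgenual-cingulate seed-map computation, voxelwise
    brain-behavior correlation with Monte-Carlo cluster-extent correction,
    and cross-cohort replication masking. A two-cohort synthetic data
    generator with known ground truth makes every stage testable without
    access to raw phone or MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
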