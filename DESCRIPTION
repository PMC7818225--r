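Package: erpmass
Title: Mass-Univariate Scalp-Time Analysis of ERP Repetition Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical-parametric-mapping style analysis of event-related
    potential (ERP) repetition effects. Epoched EEG is preprocessed into
    per-condition mean ERPs, interpolated onto a 32x32 pixel scalp map for
    every time point to form smoothed scalp-by-time image volumes, and
    modelled voxelwise with single-subject general linear models whose
    parametric modulators encode exponential, linear, or categorical
    ("change detection") repetition dynamics. Group inference uses one-sample
    F tests with voxel-level family-wise error correction by random field
    theory, and models are compared voxelwise through the Bayesian
    information criterion approximation to the log model evidence, summed
    over subjects into log group Bayes factors. A synthetic multi-subject
    ERP generator with known ground-truth repetition dynamics makes every
    stage testable without access to recorded EEG.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
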