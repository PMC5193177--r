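Package: gmpool
Title: Multi-Center Gray-Matter Pattern Classification for Psychosis Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools voxel-based-morphometry gray-matter probability maps from
    multiple MRI acquisition sites and asks whether a linear maximum-margin
    classifier can predict subject characteristics (sex, or continuous versus
    remitting illness course after a first psychotic episode). Implements
    outcome labelling from follow-up episode/remission histories, Gaussian
    smoothing and gray-matter masking of probability volumes, linear
    support-vector classification with nested cross-validated selection of the
    penalty parameter, site-matched leave-two-out cross-validation, balanced
    bootstrap subsampling, positive/negative predictive accuracy, and
    permutation significance testing. Ships a synthetic multi-site
    gray-matter-map generator with planted site, sex and illness-course
    effects for calibration and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
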