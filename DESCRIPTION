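Package: perfcad
Title: Single-Subject Computer-Aided Diagnosis from Arterial Spin Labeling Perfusion Maps
Version: 0.1.0
Authors@R:
    person("perfcad", "developers", email = "perfcad@example.org", role = c("aut", "cre"))
Description: Voxel-based normative analysis of pulsed arterial spin labeling
    (PASL) cerebral blood flow maps for single-subject detection of
    Alzheimer-type hypoperfusion. Fits an element-wise Gaussian reference
    model of a healthy cohort, derives per-subject T-score and
    likelihood-of-hypoperfusion maps, corrects them with gray-matter and
    PCA-regression predictive priors, classifies subjects with a
    two-threshold discriminant rule tuned by leave-one-out grid search
    (plus a radial-basis max-margin classifier), and accumulates
    hypo-perfused voxels over an anatomical atlas. Includes a synthetic
    cohort generator with planted lesions so the full pipeline is testable
    without clinical data, and minimal NIfTI-1 volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
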