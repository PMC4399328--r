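Package: soundloc3d
Title: Decoding Three-Dimensional Sound Location from fMRI Multivoxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multivariate pattern analysis of sparse-sampling
    auditory fMRI experiments on 3D sound localization. Simulates multi-run
    datasets with planted, condition-specific multivoxel activation patterns
    inside a temporal-lobe-like region of interest; estimates per-run,
    per-location response amplitudes with a canonical double-gamma HRF general
    linear model; selects informative voxels by fitting Gaussian nulls to
    linear support-vector-machine weights under label permutation; decodes
    left/right, up/down and front/back sound location with leave-one-run-out
    cross-validation; and aggregates effective voxels across runs and subjects
    with an exact binomial tail bound. Volumes are read and written as NIfTI-1,
    event tables as tab-separated text, and configurations and reports as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    matrixStats,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
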