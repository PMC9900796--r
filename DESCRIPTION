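Package: dynmap
Title: Mapping Regional Neurophysiological Dynamics onto Cortical Micro-Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping regional neurophysiological (MEG-like)
    time-series with a curated feature catalog, parameterizing power spectra
    into aperiodic (knee) and oscillatory components to estimate intrinsic
    timescales and oscillation scores, extracting dominant spatial gradients
    of dynamics with principal component analysis, and statistically relating
    dynamics to micro-architectural brain maps with partial least squares,
    spatial-autocorrelation-preserving ("spin") permutation nulls, bootstrap
    confidence intervals, and distance-dependent cross-validation. Includes
    Allen-Human-Brain-Atlas-style expression processing (probe filtering,
    differential-stability probe selection, robust-sigmoid normalization,
    sample-to-parcel assignment, cell-class mean maps) and a fully seeded
    synthetic-data generator with known ground truth so the entire pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
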