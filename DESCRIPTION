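Package: brainpolarity
Title: Whole-Brain Polarity Regime Dynamics for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of whole-brain "polarity" dynamics in voxelwise-normalized
    BOLD fMRI. Each gray-matter voxel time series is z-scored and discretized
    into intrinsic activation levels {-1, 0, +1}; per-TR proportions of high,
    low and neutral voxels are clustered into dynamic polarity regimes;
    voxelwise polarity participation maps, brainwide co-polarization patterns
    with a conservative Gaussian significance test, most-probable state
    itineraries, and sliding-window network connectivity statistics with
    nuisance-corrected group regressions are built on top. Includes a
    synthetic 4D cohort generator emulating the statistical structure the
    analysis assumes, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
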