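Package: phasewave
Title: Fourier Analysis of Phase-Encoded fMRI and Hemodynamic Traveling Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for rapid phase-encoded fMRI experiments with periodic
    task designs. Computes per-voxel and per-vertex Fourier F-statistics at
    the task frequency, phase angles, and complex F-values; vector-averages
    complex activation maps across scans and subjects; analyses hemodynamic
    traveling waves on flattened cortical meshes via phase-gradient vector
    fields, isophase bands, and movie-frame masks; derives surface-ROI surge
    profiles with arrival, ending, latency, and peak metrics; and ships a
    synthetic BOLD simulator with planted delays and traveling waves that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
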