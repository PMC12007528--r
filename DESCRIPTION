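Package: dianasim
Title: Digital-Phantom Simulation and Analysis of Loop-Swapped DIANA fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ultrafast single-slice fMRI acquisitions in which the
    phase-encoding and measurement loops are swapped (the DIANA scheme) next to
    conventional spoiled gradient-recalled echo (SPGRE) imaging, using a 2D
    digital phantom with configurable steady-state tissue signals, a
    millisecond-scale functional response, scanner drift, noise and rigid
    in-plane motion. Includes a Bloch engine for steady-state and dummy-pulse
    planning, k-space sampling and reconstruction, 2D rigid motion correction,
    and the trial-averaged statistical analysis chain (per-trial normalization,
    percent signal change, detrending, Gaussian smoothing, ROI aggregation,
    confidence intervals, temporal SNR and detectability, and a Fourier-domain
    BOLD localizer).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
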