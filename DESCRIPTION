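Package: sfdi
Title: Spatial Frequency Domain Imaging Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for spatial frequency domain imaging (SFDI):
    demodulation of three-phase structured-illumination frame stacks,
    calibration against a characterized tissue-mimicking phantom, per-pixel
    inversion of two-frequency diffuse reflectance to absorption and reduced
    scattering maps via a lookup table, oxy/deoxyhemoglobin chromophore
    unmixing, and phase-stepping profilometry. Includes a diffusion-theory
    forward model with a photon Monte Carlo cross-check, a synthetic raw-data
    simulator for end-to-end validation, and the agreement statistics
    (Bland-Altman limits of agreement, percent difference, drift summaries)
    used to characterize SFDI instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    tibble,
    stats,
    utils,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
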