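Package: eacmap
Title: Effective Attenuation Coefficient Mapping from Multi-Distance
    Continuous-Wave Near-Infrared Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for estimating the optical
    effective attenuation coefficient (EAC) of head tissue from multi-distance
    continuous-wave near-infrared intensity recordings. Provides a synthetic
    cohort generator built on the semi-infinite diffusion forward model
    (channel intensities with shot noise, physiological oscillations and
    optode gain heterogeneity), signal preprocessing and SNR computation,
    neighborhood multi-distance EAC estimation with topographic disk mapping,
    dual-wavelength tissue-oxygenation inversion, wavelength-space principal
    component decomposition, and an association battery with partial
    correlations and Baron-Kenny mediation with the Sobel test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    interp,
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
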