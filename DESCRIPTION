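Package: paoxy
Title: Spectral Photoacoustic Oximetry with Second Near-Infrared Wavelengths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modeling and analysis of spectral photoacoustic
    oximetry through scattering tissue. Provides packaged chromophore
    spectra (oxy/deoxyhemoglobin, water, lipid), a voxelized Monte Carlo
    photon-transport solver and a one-dimensional diffusion surrogate for
    optical fluence, synthetic digital replicas of a blood-tube phantom and
    a layered abdomen, isosbestic and fluence normalization of
    region-of-interest spectra, linear spectral unmixing of hemoglobin
    oxygen saturation, laser-safety exposure limits, and a replicated
    comparison of first versus second near-infrared wavelength sets by
    total absolute saturation error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
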