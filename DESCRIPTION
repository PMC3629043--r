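Package: waveopt
Title: Wavelength Selection for Quantitative Diffuse Reflectance Spectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for choosing a minimal set of illumination center
    wavelengths for quantitative spectral imaging of tissue. Provides
    forward models of probe-geometry diffuse reflectance (an
    extrapolated-boundary dipole diffusion solution and a scaled
    photon-record Monte Carlo), bound-constrained inverse extraction of
    chromophore concentrations (oxy- and deoxy-hemoglobin, beta-carotene)
    and reduced scattering, a genetic algorithm that searches wavelength
    subsets by minimizing extraction error against full-spectrum
    references, Gaussian bandpass degradation studies, tissue-mimicking
    phantom designs, and agreement statistics (Bland-Altman, rank-sum,
    margin-map classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
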