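Package: skindpf
Title: Monte Carlo Estimation of Differential Pathlength Factors in Layered Skin
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Weighted-photon Monte Carlo transport through a seven-layer model
    of human skin in reflection geometry, for near-infrared spectroscopy
    applications. Builds wavelength-resolved absorption coefficients from
    chromophore volume fractions (water, hemoglobin, melanin), propagates
    photon packets with Henyey-Greenstein scattering and Fresnel boundaries,
    and converts detected-photon pathlengths into differential pathlength
    factors (DPF) across wavelength and source-to-detector separation,
    per-layer partial pathlengths, replicate statistics, and banana-shaped
    spatial sensitivity maps. Includes independent reference oracles (a scalar
    random walker and the semi-infinite diffusion closed form) used by the
    built-in physics validation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
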