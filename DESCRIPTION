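Package: svaflux
Title: Detection of Soil Water Vapor Adsorption from Eddy-Covariance Flux Towers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects soil water vapor adsorption (SVA) events in half-hourly
    eddy-covariance records. Nighttime latent heat flux directions are binned
    in (atmospheric relative humidity x volumetric soil water content) space
    and compared against a family of vapor-equilibrium boundary templates
    derived from the Kelvin equation; the best-fitting template per site is
    selected by classification accuracy against a null baseline, and SVA
    occurrence is summarized as days per year and hours per day. Includes a
    reader for FLUXNET-style half-hourly CSV files, the quality and
    meteorological filters the analysis requires, and a synthetic tower-data
    generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
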