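Package: eisr
Title: Resolution Analysis for Born-Approximation Electromagnetic Inverse
    Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative resolution analysis in two-dimensional
    electromagnetic inverse scattering as used in microwave medical imaging.
    Implements a pulse-basis method-of-moments forward solver for transverse
    magnetic scattering, the two-step Born-approximation inversion (truncated
    singular-value minimum-norm current followed by least-squares contrast
    recovery), the squared-Bessel point spread function and general spread
    functions of extended scatterers, and Rayleigh, Sparrow and modified
    Sparrow two-scatterer resolution criteria, including the inverse query
    for the cylinder radius achieving a target resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
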