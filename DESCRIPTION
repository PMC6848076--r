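Package: anemovis
Title: Visual Ecology Modelling for Reef Fish: Receptor-Noise Colour
    Discrimination, Opsin Expression and Retinal Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the visual system of coral reef fish,
    built around the anemonefish case: spectral data handling and lens
    transmission (T50), visual pigment absorbance templates and lambda-max
    estimation (from measured absorbance or amino-acid tuning sites),
    quantum catches and receptor-noise-limited chromatic and luminance
    discrimination in just-noticeable differences, opsin gene expression
    proportions, design-based retinal stereology with Gaussian-kernel
    topographic maps and coexpression-region detection, spatial resolving
    power and detection distances, and seeded synthetic-data generators
    that emulate the statistical structure of each input so the whole
    pipeline is testable without measurement data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
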