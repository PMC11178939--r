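Package: flagwave
Title: Quantification of Flagellar Waveforms from Traced Coordinates
Version: 0.1.0
Authors@R:
    person("Flagwave", "Maintainers", email = "flagwave@posteo.net",
           role = c("aut", "cre"))
Description: Quantifies planar flagellar beating from manually traced
    head-to-tip coordinate sequences. Computes arc-length parameterized
    tangent-angle profiles, decomposes the beat into a static component
    (basal curvature, the slope of a pooled linear fit of tangent angle
    on arc length) and a dynamic component, estimates signed curvature by
    sliding circle fits and summarizes bend asymmetry as the ratio of the
    extreme curvatures at a fixed arc position, estimates beat frequency
    spectrally, and compares groups with Welch t tests adjusted by the
    Holm-Bonferroni method. Includes a traveling-curvature-wave simulator
    that renders pixel-quantized noisy traces with known ground truth so
    every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
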