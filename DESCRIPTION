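Package: evostereo
Title: Evolving Binocular Disparity Networks from Anatomical Correspondence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of binocular disparity coding based on
    anatomically corresponding retinal points rather than image matching. The
    package renders a minimal stereo environment (fronto-parallel luminous
    boundaries projected onto paired sensor arrays), drives fixed ON-center /
    OFF-surround monocular units, and evolves second-order (absolute
    disparity) and third-order (relative disparity) binocular sigmoid units
    with a genetic algorithm using roulette-wheel selection and parameter
    exchange. Probe utilities measure disparity tuning curves, ocular
    dominance indices, connection-sign signatures, operational disparity
    limits, responses to anti-correlated stereograms, and a retinotopy
    control verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
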