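Package: beebuzz
Title: Acoustic Monitoring of Bumble Bee Flight Buzzes and Pollination Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects bumble bee flight buzzes in field audio recordings with a
    computational auditory scene analysis (CASA) pipeline: harmonic focal
    templates select candidate time-frequency bins, spectral clustering groups
    them, and density and "smashed cluster" gates decide which clusters are
    buzzes. Extracts the characteristic (first-harmonic, wing-beat) frequency
    of each buzz, relates it to pollinator functional traits (wing length,
    tongue length) with mixed-effects regression and marginal r-squared, and
    quantifies pollination services from buzz density via pollinator-exclusion
    t-tests and seed-set analysis of covariance. Includes a synthetic-data
    module that generates harmonic buzz audio, soundscapes with known ground
    truth, bee trait populations, and plot-level survey and seed-set tables
    so every stage can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    nlme,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
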