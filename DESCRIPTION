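Package: sonarbeam
Title: Angular Information in Biosonar Emission Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the angular (azimuth/elevation) information
    carried by the directional emission beam of an echolocating bat. Synthesizes
    frequency-modulated echolocation calls, propagates them through a circular-piston
    emitter model, estimates a reflector's off-axis angle from the echo amplitude
    spectrum by maximum likelihood, and scores localization performance by the
    correlation main-lobe width (accuracy), the peak-to-side-lobe ratio (ambiguity),
    the Cramer-Rao lower bound, and seeded Monte Carlo error simulations. Includes
    species presets for five vespertilionid bats, mouth-gape and signal-design
    experiments, a gamma-tone auditory front end, and a command-line interface with
    CSV/JSON writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
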