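Package: ventmech
Title: Per-Breath Respiratory Mechanics and PEEP Titration from
    Ventilator Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for breath-by-breath identification of respiratory
    mechanics from ventilator pressure/flow waveform streams. Parses
    breath-delimited ("BS"/"BE") waveform captures, quarantines corrupted
    or non-physiological breathing cycles, fits the single-compartment
    lung model (elastance, resistance, offset pressure) by least squares
    on the inspiratory portion of each breath, computes the time-varying
    elastance curve and its inspiration-time-normalised area ("stiffness"),
    and analyses step-wise PEEP recruitment manoeuvres to recommend a
    patient-specific PEEP one protocol step above the minimal-elastance
    PEEP on the decremental limb. A seeded synthetic-lung simulator
    generates volume-control ramp-flow sessions, recruitment-manoeuvre
    protocols, spontaneous-effort artifacts and stream corruptions, so the
    whole pipeline is verifiable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
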