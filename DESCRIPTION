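Package: pyloric
Title: Pyloric Rhythm Frequency and Phase Analysis Under Temperature
    Steps and Ih Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rhythmic motor-circuit
    electrophysiology of the crustacean stomatogastric ganglion: burst
    detection from labeled spike trains, pyloric cycle and phase
    extraction, Q10 temperature-sensitivity fitting on holding-temperature
    frequency means, moving-average classification of non-monotonic
    frequency transients ("jags") during temperature ramps,
    phase-constancy slope inference, and quantification of the
    hyperpolarization-activated inward current (Ih) from voltage-clamp
    hyperpolarizing steps.  Includes a synthetic generator for
    temperature step protocols, triphasic PD/LP/PY spike trains, and
    voltage-clamp current traces so that every stage of the pipeline is
    verifiable without laboratory recordings, plus normality-gated paired
    inference and report assembly.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
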