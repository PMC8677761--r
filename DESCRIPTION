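Package: swarmtone
Title: Flight-Tone Tracking and Harmonic Convergence Analysis of Mosquito
    Swarm Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the acoustics of Anopheles gambiae mating
    swarms. Tracks male and female flight-tone fundamentals in swarm
    recordings via short-time Fourier spectrograms with sub-bin peak
    interpolation, performs spectral-subtraction noise reduction from a
    silent lead-in profile, detects mating-interaction tones by three
    criteria (frequency excursion, amplitude excursion, rapid frequency
    modulation), classifies male-female harmonic frequency-difference
    outcomes at four harmonic ratios across interaction phases, synthesizes
    artificial swarm-tone playback stimuli, and computes the associated
    contingency statistics. Includes a seeded synthetic swarm-audio
    generator with ground-truth event logs so every stage can be validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
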