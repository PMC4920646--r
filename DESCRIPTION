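Package: swdquant
Title: Detection, Spectral Analysis and Quantification of Spike-and-Wave
    Discharges in Rodent EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of absence seizures in rodent models
    such as the Genetic Absence Epilepsy Rat from Strasbourg (GAERS):
    semi-automatic amplitude-threshold detection of spike-and-wave
    discharges (SWDs) with grouping, amalgamation, duration and
    instantaneous-frequency criteria; Morlet continuous-wavelet ridge
    extraction of ictal peak frequency; masked interictal band-power
    analysis by Gaussian-window short-time Fourier transform; per-epoch
    seizure quantification with control-period and vehicle-group
    normalization; and the associated statistical battery (two-way ANOVA,
    Dunnett and Sidak post-hoc contrasts, unpaired t-tests). A synthetic
    EEG generator produces GAERS-like sessions with ground-truth
    annotations and parametric drug-effect models so that every pipeline
    stage can be validated end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    car,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
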