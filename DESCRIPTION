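Package: chirpent
Title: Chirp-Evoked EEG Entrainment and TMS Cortical Excitability Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for auditory chirp steady-state EEG experiments
    and paired-pulse transcranial magnetic stimulation (TMS) protocols.
    Implements the full chain from raw multi-channel recordings to group
    statistics: zero-phase bandpass/notch filtering, channel and epoch
    artifact rejection, region-of-interest averaging, complex Morlet wavelet
    time-frequency decomposition, event-related spectral perturbation (ERSP)
    and inter-trial coherence (ITC) maps, ITC-threshold mask construction
    with frequency-band extraction, one-way ANOVA with Tukey or Games-Howell
    post-hoc routing, and EMG-based TMS outcome measures (peak-to-peak motor
    evoked potentials, paired-pulse inhibition/facilitation ratios, cortical
    silent period, input/output curves). A synthetic-data module generates
    chirp stimuli, trial schedules, EEG sessions with controllable
    phase-locked entrainment, and EMG trial sets so every stage is testable
    without patient data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
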