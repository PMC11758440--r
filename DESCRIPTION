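Package: ztefmri
Title: Neurovascular Coupling Analysis for Zero Echo Time fMRI with
    Simultaneous Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing simultaneous zero echo time (zero-TE)
    functional MRI and intracranial EEG recordings from rodent
    somatosensory stimulation experiments.  Implements gradient-artifact
    template subtraction, band-pass and notch filtering, instantaneous
    power, epoching and baseline correction for the electrophysiology
    side; 100-s high-pass detrending, region-of-interest time-course
    extraction and event-reordered radial-spoke rebinning for the fMRI
    side; a shifted gamma-density hemodynamic impulse response function
    (IRF) with grid-search convolution fitting, numerical
    characterisation (onset time, time-to-peak, full width at half
    maximum) and reference IRFs from the literature; and response-size
    and time-course regression analyses of fMRI-neuronal coupling across
    stimulation frequencies.  A synthetic-data generator emulates the
    stimulation paradigms, evoked waveforms with frequency-dependent
    adaptation, MRI gradient artifacts, line noise and IRF-convolved
    fMRI responses, so the whole pipeline is testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
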