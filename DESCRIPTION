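Package: voltimg
Title: Analysis Toolkit for Widefield Voltage Imaging with Genetically Encoded Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluorescence recordings from genetically encoded
    voltage indicators (GEVIs): high-throughput screening analytics (background and
    mask estimation, multi-term exponential photobleaching detrending,
    SNR-maximising responsive-pixel selection, response amplitude, brightness and
    photostability metrics, excitation/emission spectra processing),
    exponential-with-onset kinetics fitting and time-constant reporting for
    voltage-clamp step responses, threshold-based spike detection with
    precision/recall/F1 scoring, a dual-channel widefield preprocessing pipeline
    that removes heartbeat and slow hemodynamic artifacts by sequential
    band-filtered reference regression, and spectral analyses (Welch power spectral
    density, stimulation-frequency power-difference maps, magnitude-squared
    coherence, LFP correlation maps with shuffled controls). Includes seeded
    synthetic-data generators emulating the statistical structure of dual-channel
    widefield movies, patch-clamp-style step and spike-waveform fluorescence
    traces, and screening fields of view, so that every stage can be exercised and
    validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    rhdf5,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
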