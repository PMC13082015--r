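Package: voltscope
Title: Analysis of Two-Photon Genetically Encoded Voltage Indicator Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete analysis stack for fluorescence voltage imaging:
    synthetic data generation with ground truth (membrane-voltage waveforms,
    sigmoid fluorescence-voltage coupling with on/off kinetics, Poisson photon
    emission, movie rendering, stimulus-locked and freely-moving populations),
    movie and trace preprocessing (background estimation, two-step phase
    correlation motion correction, correlation-based pixel selection,
    multi-exponential photobleach fitting with AIC/BIC model selection,
    several dF/F baseline conventions), high-throughput screening metrics
    (relative brightness, response amplitude, photostability AUC,
    detectability indices), biophysical model fitting (step-response
    exponential kinetics, fluorescence-voltage sigmoid, spike waveform
    metrics, downsampling analysis), three optical spike detectors
    (adaptive kernel-density threshold, delayed-differential kHz detector,
    sliding-standard-deviation detector) with event post-processing,
    ground-truth evaluation against electrophysiology (spike matching,
    precision-recall curves, subthreshold correspondence), stimulus-locked
    functional mapping (pixelwise orientation tuning, visual responsiveness,
    phase binning and cross-correlation against neuromodulator signals), and
    freely-moving spatial analysis (kinematics, occupancy-normalized rate
    maps, border score, circular-shuffle significance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    pracma,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    withr
Config/testthat/edition: 3
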