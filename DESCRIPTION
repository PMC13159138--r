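Package: wellcal
Title: Multi-Well Calcium Imaging Analysis: dF/F0, Deconvolution, Events,
    Networks and Evoked Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis engine for high-content calcium imaging of neuronal
    cultures in multi-well plates. Extracts per-soma fluorescence traces from
    time-lapse videos and instance label masks, computes dF/F0 against a
    sliding-window percentile baseline, denoises and deconvolves traces under
    a non-negative AR(1) model (OASIS), detects calcium transients with
    noise-adaptive height and prominence thresholds, derives single-cell
    features (amplitude, event frequency, inter-event interval, cell size,
    activity status), quantifies network synchrony through pairwise Pearson
    correlation with stimulation-epoch restriction, and analyses
    optogenetically evoked responses (stimulated-ROI classification,
    pulse-peak matching, LED power calibration, irradiance-response curves).
    Includes instance-segmentation evaluation metrics (Dice, Panoptic
    Quality, SoftPQ, mAP) and a fully parameterised synthetic-data generator
    with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
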