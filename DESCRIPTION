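Package: palmbp
Title: Non-Contact Blood Pressure Estimation from Palm Video Pulse Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for camera-based (remote photoplethysmography) blood
    pressure estimation from the palm. Provides a harmonic pulse-waveform
    simulator and synthetic cohort generator, region-of-interest channel
    trace extraction from hand landmarks, FastICA-based denoising with
    semi-blind unmixing, peak/valley pulse feature extraction with a
    refractory-interval filter, blood-pressure formula calibration by a
    hybrid Nelder-Mead particle swarm optimizer and by ordinary least
    squares regression, and device-validation metrics (MAE, MAPE, RMSE,
    AAMI pass/fail, BHS letter grading).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
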