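Package: mfudsa
Title: Multifrequency Ultrafast Doppler Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional (fast-time by slow-time) multifrequency Doppler
    spectral estimation for ultrafast pulsed-wave ultrasound, with spectral
    scaling and averaging across the transmitted bandwidth. Includes a
    synthetic in-phase/quadrature (IQ) data simulator with known ground-truth
    velocity waveforms, a conventional one-dimensional spectral-Doppler
    baseline, signal-to-noise and velocity-resolution benchmarking, wall
    shear stress estimation by velocity-gradient and parabolic (Poiseuille)
    methods, and a reproducible simulate-analyze-report pipeline with an
    open binary IQ container format.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
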