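Package: cyclorhythm
Title: Cycle-Aligned Statistical Analysis of Rhythmically Connected
    Multichannel Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models multichannel electroencephalographic (EEG) recordings
    acquired under repeated mental-control trials as a vector of cyclic
    rhythmically connected random processes. Provides piecewise-linear
    estimation and validation of the irregular rhythm function, cycle-aligned
    statistical estimation of mean, dispersion and higher-order initial,
    central and mixed moment functions, Butterworth notch and band-pass
    preprocessing, Fourier spectra of the estimates with Bessel-inequality
    feature reduction, activity-versus-passivity zone sensitivity scoring,
    and a synthetic-signal simulator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
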