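Package: ssaeeg
Title: Singular Spectrum Analysis of Anesthetic EEG with Hilbert Spectral Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mode decomposition of single-channel frontal electroencephalogram
    (EEG) recordings acquired during general anesthesia. Short overlapping
    epochs are embedded into a Hankel trajectory matrix, decomposed by singular
    value decomposition, and eigentriples are grouped and diagonally averaged
    into six intrinsic mode functions (IMFs). Hilbert spectral analysis of each
    IMF yields instantaneous amplitude and frequency, summarised per epoch as a
    center frequency (Hz) and total power (dB). The twelve resulting parameters
    feed a multiple linear regression of a depth-of-anesthesia index (BIS),
    with significance-based model reduction, phase summaries, and a synthetic
    anesthesia-like EEG generator with a programmed BIS-like index for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
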