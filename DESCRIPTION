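Package: nmraudify
Title: Audification of NMR Free-Induction Decays with Frequency-Domain
    Zero-Padding Anti-Aliasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Renders NMR free-induction-decay (FID) data as audio whose
    pitches match the frequencies observed in the spectrum.  Implements a
    frequency-domain zero-padding (ZPFD) procedure that eliminates the
    aliasing produced when only the real channel of a quadrature-detected
    FID is played back, a reference-offset correction, exponential
    apodization and zero-filling, Lorentzian peak picking, and region-wise
    sub-FID resynthesis for acoustic interpretation of spectral regions
    (aliphatic, olefinic, aromatic).  Includes a Lorentzian FID simulator
    so the full pipeline runs without instrument data, a 16-bit PCM WAV
    writer and reader, an audio frequency analyzer, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
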