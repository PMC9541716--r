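Package: pacemap
Title: Spatiotemporal Analysis of Pacemaker Activity in Cardiomyocyte
    Monolayers on Stretchable Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse spontaneous electrical activity recorded from
    cardiomyocyte monolayer cultures on 12-electrode stretchable
    microelectrode arrays. Detects activation times from unipolar
    extracellular electrograms (median/AC-coupling/Kaiser filtering,
    derivative-minimum detection, fusion of fractionated deflections),
    clusters activations into beats, and derives interbeat-interval series,
    integral-preserving instantaneous beat-rate resampling, conduction
    slowness vectors by least-squares plane fitting, Shannon entropy of the
    slowness distribution, principal-component analysis of activation
    patterns, and detrended fluctuation analysis of beat-rate variability.
    Includes epoch averaging of the beat-rate response to stretch/release
    protocols, the accompanying statistical tests, and a ground-truthed
    synthetic-recording generator (competing peripheral pacemaker foci with
    fractal period noise) for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
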