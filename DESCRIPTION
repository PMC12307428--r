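Package: fingereeg
Title: Multi-Domain EEG Feature Extraction and Classification of Finger Movement Imagery
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying five-finger motor-imagery EEG plus a no-task
    baseline from 19-channel, 1 s epochs sampled at 1000 Hz. Implements a
    1102-feature extraction pipeline over four domains (24 time-domain
    descriptors; Fourier band energy, variance and spectral entropy over the
    five canonical EEG bands; 9-level Haar wavelet-packet band energy,
    variance and entropy; Poincare plot SD1/SD2 measures), per-feature
    one-way ANOVA significance screening, channel-by-feature significance
    distribution maps, and a multi-classifier stratified 5-fold
    cross-validation benchmark. Includes a seeded synthetic EEG generator with
    class-dependent band-power modulation for end-to-end testing, plus CSV/JSON
    input and output for every artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
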