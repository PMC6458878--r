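Package: alphadelta
Title: Individualized Alpha/Delta EEG Neurofeedback Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing individualized alpha/delta neurofeedback studies of
    chronic tinnitus: synthetic multichannel resting-state EEG and behavioral cohort
    generation, Butterworth/ICA/spline preprocessing, Welch-style spectral
    quantification with individual alpha frequency (IAF) estimation and alpha/delta
    band-power ratios, a closed-loop neurofeedback session simulator, and the
    repeated-measure mixed-model contrast analysis with effect-size conversion,
    Tukey post hoc tests, difference-score correlations and within-subject error bars.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    nlme,
    mvtnorm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
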