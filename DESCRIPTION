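Package: ifngdyn
Title: Deterministic and Stochastic Models of Interferon-Gamma-Induced Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models interferon-gamma (IFNg) induced expression of primary and
    secondary response genes (IRF1, CXCL10, CXCL9) with a three-state chromatin
    kinetic model (closed, open-uninitiated, open-initiated) driven by a
    saturating STAT1 transcription-factor input with optional negative-feedback
    adaptation. Provides deterministic ODE integration under piecewise-constant
    stimulus protocols, multi-condition constrained fitting of population-mean
    time courses, an exact direct-Gillespie single-cell simulator at
    molecule-count scale, single-cell trace feature extraction (amplitudes,
    lag times, half-max widths, tanh induction fits, CV, pulse-responder
    classification), and a synthetic single-cell dataset generator emulating
    hourly time-lapse fluorescence imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
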