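Package: photicnmm
Title: Dynamics of a Periodically Forced Jansen-Rit Neural Mass Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and dynamical charting of the normalized Jansen-Rit
    neural mass model of a cortical area under periodic pulse forcing, as used
    to explain photic driving (alpha-rhythm entrainment by flicker
    stimulation). Provides adaptive Runge-Kutta integration of the forced
    system, full Lyapunov spectra by tangent-space QR reorthonormalization,
    Kaplan-Yorke dimensions and regime classification, frequency-detuning and
    entrainment analysis, Poincare sections and bifurcation diagrams, Wolf
    fixed-evolution-time estimation of the largest Lyapunov exponent from
    (surrogate) EEG, a surrogate photic-driving EEG generator, and the
    shift-scale nearest-neighbour procedure for fitting the model's stimulus
    amplitude to per-subject exponent profiles with bootstrap significance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    signal,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
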