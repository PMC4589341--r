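Package: izhcr
Title: Chaotic Resonance Analysis of the Izhikevich Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and dynamical analysis of the Izhikevich spiking
    neuron, a hybrid (flow plus reset) system. Provides event-detecting
    stiff integration with co-propagated variational equations, Lyapunov
    spectra corrected with saltation matrices at the state-dependent reset,
    Poincare return-map analysis on the firing section (fixed points,
    stability index, tangent-bifurcation localization, intermittency
    statistics), and weak-signal response metrics for chaotic resonance:
    cycle histograms, lagged mutual correlation, and mutual information
    between spike phase histograms and a periodic input. Includes
    synthetic spike-train and linear hybrid-system generators with
    closed-form properties for calibrating every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
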