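Package: serabm
Title: Agent-Based SER Simulation of Signed Brain Functional Connectivity
Version: 1.0.0
Authors@R: person("Fabio", "Serra", email = "fserra@example.org", role = c("aut", "cre"))
Description: Simulates large-scale brain activity with an agent-based model in
    which every region cycles through susceptible, excited and refractory (SER)
    states while being modulated by positively and negatively weighted
    functional-connectivity links. Provides signed Pearson connectivity
    estimation from region-by-time panels, absolute-value and signed
    proportional thresholding of correlation matrices into ternary networks,
    a goodness-of-fit protocol that scores simulated against empirical
    connectivity over replicate runs, grid sweeps across dynamical parameters
    and network costs, a nonparametric significance layer (Friedman test with
    Tukey-Kramer post hoc on rank means), and a synthetic-data generator that
    emulates multi-subject resting-state panels with modular positive structure
    and cross-module anticorrelations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
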