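Package: riskcoev
Title: Coevolutionary Dynamics of Cooperation and Risk in Collective-Risk Social Dilemmas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulator and analysis toolkit for threshold public-goods games in
    which the risk of collective failure is itself a dynamical variable coupled
    to the strategy frequencies. Implements replicator dynamics for the
    cooperator frequency together with linear or sigmoidal (exponential)
    strategy-to-risk feedback, exact binomial payoff expectations, analytic
    fixed-point enumeration and Jacobian-based stability classification, Hopf
    bifurcation thresholds with numerical cross-checks, the first Lyapunov
    coefficient for supercriticality, parameter-plane region classification,
    stiff ODE trajectory integration with limit-cycle detection, and basin-of-
    attraction mapping. Includes named parameter presets and a small command
    line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
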