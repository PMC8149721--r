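Package: crkinetics
Title: Growth and Reduction Kinetics for Cr(VI) Cometabolism in Batch Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic analysis of microbial hexavalent-chromium reduction in
    batch reactors with cometabolic substrates (glucose and high-carbon iron
    filings). Provides forward evaluation and nonlinear least-squares fitting
    of pseudo-first/second-order decay laws, the Haldane-Andrews
    substrate-inhibition growth model, and a three-substrate Monod growth
    model with nine cross-inhibition constants; log-linear specific-growth-rate
    estimation with automatic exponential-phase window selection; a
    batch-reactor ODE simulator for generating ground-truth time courses; and
    an end-to-end analysis pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
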