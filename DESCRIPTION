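Package: isruq
Title: Agent-Based In-Stent Restenosis Simulation with Quasi-Monte Carlo
    Uncertainty Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional multiscale simulator of in-stent restenosis
    (stent deployment mechanics, smooth muscle cell proliferation,
    re-endothelialization and flow-derived wall shear stress inhibition)
    together with a variance-based uncertainty-quantification toolkit:
    Sobol low-discrepancy sampling, the Saltelli M(2n+2) evaluation design,
    estimators for first-order and total sensitivity indices with an
    aleatory/epistemic decomposition, and bootstrap error bars. Campaign
    tools generate, execute and analyze ensembles of independent runs,
    producing uncertainty bands, final-area distributions, sensitivity-index
    time series and spatial presence-probability and sensitivity maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
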