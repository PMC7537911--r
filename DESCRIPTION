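Package: caosc
Title: Calcium Oscillations in Cardiac Calcium Release Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Minimal models of calcium cycling in a cardiac calcium release
    unit (CaRU): a three-variable deterministic model of dyadic calcium, total
    sarcoplasmic-reticulum (SR) calcium and ryanodine-receptor (RyR) open
    fraction, together with its fast-RyR and fast-dyadic two-variable
    reductions, an exactly mass-conserving rapid-buffer treatment of
    calsequestrin, and uniform per-step RyR gating noise. Tools map the total
    cell calcium load and buffering levels to dynamical regimes: fixed points
    and their linear stability, bifurcation sweeps locating the fold,
    homoclinic and Hopf loci, nullcline geometry and pinch-off detection,
    closed-form onset-of-oscillation formulas with cytosolic-buffer
    dependence, noise-sustained oscillations below the deterministic onset,
    and a small diffusively coupled lattice of stochastic units for
    qualitative calcium-wave phenomenology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
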