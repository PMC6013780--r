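Package: cryptDrift
Title: Neutral-Drift Stem Cell Dynamics and mtDNA Clonal Expansion in Human Colonic Crypts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-scale stochastic simulation and analytic modelling of clonal
    lineage dynamics in the human colonic crypt stem-cell niche, using somatic
    mitochondrial DNA (mtDNA) mutations that cause oxidative-phosphorylation
    (OXPHOS) deficiency as a neutral clonal mark. Simulates relaxed replication
    and random segregation of mtDNA within dividing stem cells embedded in a
    ring-shaped niche with asymmetric or symmetric division fate outcome; solves
    the one-dimensional neutral-drift birth-death master equation for clone size
    with time-increasing clone induction; maps stem-cell-level clonal states to
    histological section fractions; generates synthetic biopsy cohorts; and fits
    effective stem-cell number, loss/replacement rate, induction parameters and
    the asymmetric fate-outcome probability to decade-binned crypt data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
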