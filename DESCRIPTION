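Package: gblcircuit
Title: Ensemble Modelling of the Streptomyces gamma-Butyrolactone scbR/scbA Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic ODE modelling of the gamma-butyrolactone (GBL)
    signalling circuit of Streptomyces coelicolor. Assembles a unified
    meta-model of the divergent scbR/scbA gene pair (transcriptional
    interference between overlapping promoters, antisense mRNA duplex
    formation, a hypothetical ScbA-ScbR activator complex, and a dual
    repressor/activator role of ScbR) into eight switchable scenarios,
    couples the kinetics to Baranyi-Roberts culture growth, simulates
    ensembles of parameter sets drawn from log-normal priors, scores each
    member by total log-likelihood against transcript-profile and
    activation-threshold targets (prior predictive check), and tests which
    parameter regions are enriched among high-scoring models
    (Kolmogorov-Smirnov tests with Bonferroni control, bin-wise binomial
    tests with Benjamini-Hochberg FDR). Includes a synthetic-data generator
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
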