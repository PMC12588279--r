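Package: finmix
Title: Genetic Market Surveillance and Trade Reconciliation for CITES-Listed Sharks
Version: 0.1.0
Authors@R:
    person("Market Surveillance", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring the international shark fin trade from
    retail-market survey and trade-ledger data. Implements Bayesian
    mixed-stock analysis of mitochondrial control-region haplotype
    frequencies (Dirichlet-multinomial Gibbs sampler with an EM
    conditional-MLE cross-check and Gelman-Rubin convergence diagnostics),
    amplicon merging and haplotype assignment for degraded market samples,
    AMOVA-style pairwise Phi-ST permutation tests for population
    delimitation, binomial-logit incidence trend models for vendor-visit
    survey designs, and reconciliation of CITES-style trade records against
    customs import totals including nation-level compliance flagging.
    Seeded synthetic-data generators reproduce the statistical structure of
    every input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
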