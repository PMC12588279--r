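# finmix

Market surveillance of the international shark fin trade: genetic tracing
of fins to their source populations, incidence trends of CITES-listed
species in retail surveys, and reconciliation of CITES trade reports
against customs records.

## The problem

Five threatened sharks (scalloped, smooth and great hammerhead, oceanic
whitetip, porbeagle) are listed on CITES Appendix II: their export is
legal only when certified and reported. Whether that regulation bites can
be checked from the outside, because the world's largest fin hub can be
sampled directly. Three independent signals are combined:

1. **Where do market fins come from?** Mitochondrial control-region (mtCR)
   haplotype frequencies differ among source populations, so a "mixed"
   market sample can be decomposed into population contributions without
   assigning any individual fin — mixed-stock analysis (MSA).
2. **How often do listed species appear in the market?** A vendor visit
   (two bags, 20 genotyped fin trimmings) is a Bernoulli trial; annual
   incidence follows a binomial-logit trend model.
3. **What does the paper trail say?** CITES-reported volumes, after
   filtering (kg-only, wild-caught, commercial) and partner
   reconciliation (highest reported volume wins), divided by customs
   import totals give the legal share — and a nation-level table flags
   exporters that catch listed species, appear in border seizures, and
   report nothing.

A discrepancy between signals 1–2 and signal 3 is the fingerprint of
illegal (unreported) trade.

## The model at the core

The MSA is the many-to-one Dirichlet-multinomial mixture (Pella-Masuda).
With baseline haplotype counts n[s,h] for S source populations and market
counts x[h]:

    x ~ Multinomial(M, p),   p[h] = sum_s theta[s] * q[s,h]
    theta ~ Dirichlet(alpha_theta),   q[s,·] ~ Dirichlet(alpha_q + n[s,·])

`msa_gibbs()` samples the joint posterior by latent-label Gibbs (4 chains,
100,000 iterations, 50,000 burn-in by default), reports posterior means
with 95% credible intervals and per-parameter Gelman-Rubin R-hat
(converged when max R-hat < 1.2). `msa_em()` is the independent
conditional-MLE cross-check (EM with q fixed at baseline row MLEs).
Population delimitation uses AMOVA-style pairwise Phi_ST with permutation
tests; trends use `glm`-based binomial-logit fits with Wald tests.

## Worked example

Trace a simulated 2019 market sample against the nine-population global
baseline (SWA, Car, Ant, NWA, EAt, IOc, WPa, CPa, EPa), with reported
trade only from the Western Pacific, Indian Ocean and Eastern Pacific:

```r
library(finmix)

bl  <- gen_baseline(default_source_specs(), n_per_source = 1000, seed = 31,
                    theta = c(SWA = 0.06, Car = 0, Ant = 0, NWA = 0, EAt = 0.07,
                              IOc = 0.22, WPa = 0.30, CPa = 0.10, EPa = 0.25))
mix <- gen_mixture(bl$truth, n = 2000, seed = 32)
post <- msa_gibbs(bl$counts, mix, n_iter = 8000, burn_in = 4000,
                  n_chains = 2, seed = 33, alpha_theta = 1)
summarize_contributions(post, reporting_sources = c("WPa", "IOc", "EPa"),
                        detection_floor = 0.01)
#>   source        mean         lo95        hi95 detected reporting
#> 1    SWA 0.071973776 2.858659e-02 0.114130403     TRUE     FALSE
#> 2    Car 0.002240328 5.263903e-05 0.008609622    FALSE     FALSE
#> 3    Ant 0.006037515 1.390629e-04 0.024106593    FALSE     FALSE
#> 4    NWA 0.037421501 3.035623e-03 0.088148693    FALSE     FALSE
#> 5    EAt 0.072482507 4.079968e-02 0.107921760     TRUE     FALSE
#> 6    IOc 0.222324498 1.752039e-01 0.272743939     TRUE      TRUE
#> 7    WPa 0.285880307 2.320170e-01 0.342199496     TRUE      TRUE
#> 8    CPa 0.054751393 2.874870e-02 0.087788892     TRUE     FALSE
#> 9    EPa 0.246888175 2.074154e-01 0.287432691     TRUE      TRUE
#> detected, trade reported:   IOc, WPa, EPa
#> detected, no reported trade: SWA, EAt, CPa
```

Six populations are detected in the market but only three of them have
any reported trade — the other three contributions (here ~7%, ~7% and
~5% of the market, all with lower credible bounds above the 1% floor)
have no legal paper trail.

The packaged nation table reproduces the compliance headline:

```r
flag_nations(table1_profiles())
#> 90 fin-exporting nations: 17 reported CoP16 trade, 73 (81.1%) did not
#> non-reporters implicated in seizures: 21; catch reported but no export: 13; flagged by rule: 28

market_disparity_ratio(0.7, 0.01)   # market share vs reported share
#> [1] 70
```

That last number says oceanic whitetip fins are ~70x more common in
market trimmings (0.7%) than reported imports would predict (0.01%).

## Pipeline and CLI

`run_pipeline(default_scenario(seed = 1), "out/")` executes all six
stages (simulate, haplotype, structure, msa, trends, reconcile) and
writes per-stage CSVs plus a `manifest.json` with seeds, settings and
record/exclusion tallies. The same is available from the shell via the
installed script:

```sh
Rscript inst/cli/finmix run scenario.yaml --seed 1 --out out/
Rscript inst/cli/finmix msa --baseline base.csv --mixture mix.csv \
    --iters 100000 --burnin 50000 --chains 4 --seed 1 --out msa.csv
```

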