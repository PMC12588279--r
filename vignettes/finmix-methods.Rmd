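---
title: "Methods: mixed-stock tracing and trade reconciliation for the shark fin market"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-stock tracing and trade reconciliation for the shark fin market}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

finmix implements a market-surveillance workflow for CITES Appendix
II-listed sharks: it traces fins sold in a trade hub back to their source
populations from mitochondrial control-region (mtCR) haplotype
frequencies, tracks the incidence of listed species in retail surveys over
time, and reconciles CITES trade reports against customs import totals to
flag likely unreported trade. This vignette documents the models, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## The mixed-stock model

The core estimator is a many-to-one Bayesian mixed-stock analysis (MSA).
A market sample of $M$ fins yields haplotype counts $x_h$; a baseline of
$S$ source populations provides haplotype counts $n_{sh}$. The model is
the standard Dirichlet-multinomial mixture used in fishery genetics
(Pella-Masuda): each market fin originates from source $s$ with
probability $\theta_s$ and then carries haplotype $h$ with probability
$q_{sh}$, the source's haplotype frequency. `msa_gibbs()` augments each
fin with a latent source label $z_i$ and cycles

1. $z_i \mid \theta, q \propto \theta_s\, q_{s,h(i)}$,
2. $\theta \mid z \sim \mathrm{Dirichlet}(\alpha_\theta + \text{tally}(z))$,
3. $q_{s\cdot} \mid \text{data} \sim \mathrm{Dirichlet}(\alpha_q + n_{s\cdot} + \text{tally of fins assigned to } s)$,

so baseline sampling uncertainty propagates into the contribution
estimates. Because the likelihood depends on the latent labels only
through their haplotype-wise tallies, step 1 is implemented as one
multinomial draw per observed haplotype rather than per fin, which makes
100,000 iterations per chain cheap in plain R.

**Priors.** $\alpha_\theta = 1/S$ spreads a single prior pseudo-fin over
the sources (so the prior "sample size" does not grow with $S$);
$\alpha_q = 1$ per baseline cell. Both are arguments, not constants.

**Convergence.** Four chains by default, no thinning; the classic
(non-split) Gelman-Rubin $\hat R$ is computed per contribution parameter
after discarding the burn-in, with the conventional $\hat R < 1.2$
threshold. Degenerate chains with zero within-chain variance report
$\hat R = 1$ when their means agree and $\infty$ when they do not. The
point estimate is the posterior mean with equal-tailed 95% credible
intervals.

**Cross-check.** `msa_em()` maximizes the conditional likelihood with
baseline frequencies fixed at their row MLEs — the standard EM for
mixture proportions — asserting a nondecreasing log-likelihood at every
step. On diagnostic-marker problems the two routes must agree (this is a
test, not an option).

**Excluded records.** A mixture haplotype absent from the baseline
catalogue cannot be modeled and is excluded with a logged count; this
mirrors the attrition bookkeeping any real market sample needs when only
sequences matching known global haplotypes are retained.

## Haplotyping degraded market DNA

Market fins are processed and their DNA degraded, so the informative 535
bp mtCR section is amplified as two internal fragments (388 and 168 bp).
`merge_amplicons()` rebuilds the full-length sequence, requiring the
implied overlap ($388 + 168 - 535 = 21$ bp) to agree base-for-base; an
`N` is resolved toward the concrete base on the other fragment, while two
different concrete bases are a chimera error that names the offending
positions. Haplotypes are distinct equal-length sequence strings
(`define_haplotypes()`), and market sequences are assigned to the
baseline by exact matching with `N` as a wildcard: only a uniquely
compatible haplotype is accepted, everything else is `NOVEL` and excluded
from the MSA. This is deliberately conservative — an ambiguous or novel
sequence never silently enters the mixture — and auditable, because every
exclusion is counted. Trimming to baseline coordinates uses anchored
gap-free alignment against a reference haplotype (mtCR baselines are
aligned and equal length, so indel handling is out of scope).

## Population delimitation

Whether a newly sampled region is a distinct source population is decided
with AMOVA-style pairwise $\Phi_{ST}$ and permutation tests. Distances
are raw pairwise nucleotide differences (no substitution-model
correction: the simplest defensible choice, and the default in common
AMOVA software). The two-level variance decomposition uses the standard
unbiased moment estimators, which means $\Phi_{ST}$ is slightly
*negative* (exactly $-1/(n'-1)$) when two samples are drawn from one
population — a well-known property of the estimator, asserted as such in
the tests rather than rounded to zero. A pooled sample with zero total
variance has no defined $\Phi_{ST}$ and is reported as `NA`, not 0. The
permutation p-value is $(\#\{\Phi^{perm} \ge \Phi^{obs}\} + 1)/(B + 1)$.
`delimit_population()` declares a candidate distinct only when every
pairwise test survives a Bonferroni correction (the conservative default;
configurable), and otherwise merges it into the population with the
smallest nonsignificant $\Phi_{ST}$ — the generalization of folding new
regional samples into the population whose common haplotype they share.
Defaults: 10,000 permutations for single tests, 999 within the pairwise
battery, $\alpha = 0.05$.

## Incidence trends

A trial is one vendor visit: two bags of trimmings, 20 genotyped pieces.
The focal species is "present" when at least one of the 20 trimmings
matches, so annual incidence is a binomial proportion over vendor visits
(up to 240 trials in a biweekly-sampled year, 120 in a monthly year).
`fit_trend()` fits $\mathrm{logit}(p_t) = \beta_0 + \beta_1 (t - \bar t)$
by IRLS; centering the year affects only the intercept and is done for
numerical stability. The trend is classified significant at the Wald test
with $\alpha = 0.05$ (the threshold is an argument — the red/blue
classification convention does not pin it down). Complete separation is
detected and flagged instead of silently diverging. Confidence bands come
from the delta method on the linear predictor. Both analysis windows that
appear in practice (2015–2021 and 2014–2021) are supported via the
`window` argument; neither is privileged. Goodness of fit is checked with
randomized-quantile residuals (`quantile_residual_check()`), a
lightweight stand-in for packaged residual diagnostics.

## Trade reconciliation

CITES-style records are filtered to fins of known weight (unit kg) from
wild-caught animals (source W) traded commercially (purpose T); every
exclusion carries a machine-readable reason and filtering partitions its
input exactly. Because trade is double-reported and partner volumes
disagree, volumes are summed per reporting side within each (exporter,
importer, year, taxon) key and the larger side is kept — the conservative
"highest reported volume" rule. The key granularity is a design choice:
it is the finest key both partners' reports share. Undifferentiated
genus-level records (e.g. *Sphyrna* spp.) are kept as their own taxon
rather than apportioned to species. The legal-share series divides
reported CoP16 imports by total customs fin imports per year;
`market_disparity_ratio()` expresses how many times a species'
market-trimming share exceeds its reported import share.

The packaged nation table (90 fin-exporting nations with export volume,
CoP16 range-state count, FAO/RFMO catch flag, seizure implication, and
CITES-reporting flag) drives `flag_nations()`, which applies the
three-part rule: exports unidentified fins, catches CoP16 species and/or
is seizure-implicated, and reported no CoP16 trade. The printed source
table bolds two nations inconsistently with its own stated rule (one
bolded without a catch or seizure flag, one unbolded despite meeting the
rule); the package keeps the printed typography in a `bolded_in_print`
column but the function applies the stated rule. The headline summary
counts (17 reporting, 73 non-reporting, 21 seizure-implicated
non-reporters, 13 catch-but-no-export) do not depend on the bolding.

## The synthetic world

All inputs can be simulated, with the statistical structure the analysis
assumes:

* **Baseline preset** — nine sources (SWA, Car, Ant, NWA, EAt, IOc, WPa,
  CPa, EPa) sharing 34 haplotypes, each source with a private two-haplotype
  group plus a 16-haplotype shared backbone. This mirrors the
  identifiability regime of the real global baseline (exclusive haplotype
  groups on top of shared ones), not its frequencies, which are not
  public. True frequencies are symmetric Dirichlet (concentration 1) on
  each source's allowed set; baseline counts are one multinomial draw of
  50 per source. The haplotype catalogue keeps all 34 columns even when a
  haplotype happens not to be drawn — the catalogue is literature
  knowledge, not a property of one sample.
* **Mixtures** — `gen_mixture()` draws fins exactly from the model's own
  generative process; defaults of 92 (trimmings) and 142 (small fins)
  match the sizes of the real 2019 strata, which are analyzed separately
  by default. The default truth places six of nine sources in the market,
  dominated by the Western Pacific, Eastern Pacific and Indian Ocean.
* **Surveys** — biweekly sampling in 2014 (up to 20 vendor visits per
  month), monthly thereafter (up to 10), 2 bags x 10 trimmings per visit.
  Species labels are i.i.d. within a year's composition; real bags are
  surely over-dispersed (vendor and shipment effects), so synthetic
  power estimates are optimistic. A stocking probability thins visits.
* **Ledgers** — customs totals for every nation-year; CITES records only
  for reporting nations, with injected malformed records and
  importer/exporter mismatches to exercise the filters.
* **Amplicons** — substitution-only noise; indels are excluded because
  baseline mtCR haplotypes are aligned and equal length. The substitution
  model and within-source sequence diversity are free knobs, not
  estimates of anything.

Because generators and seeds fix everything, a green test establishes
that the *algorithms* are correct in the stated world — it does not
reproduce the published market estimates, whose underlying haplotype
frequencies and per-vendor data are not printed.

**Calibration tests.** Credible-interval coverage is checked by
simulation-based calibration, which requires the truth to be drawn from
the estimation prior: the true contribution vector is drawn from
$\mathrm{Dirichlet}(1)$ and the sampler is run with
$\alpha_\theta = 1$ (the prior is an argument precisely so that such
checks are possible; the analysis default remains $1/S$). Data are
generated from the model and the 95% interval must cover at 0.95 within
Monte Carlo error. One mismatch remains by design: the generator
restricts each source's frequencies to its allowed haplotype set while
the sampler's $\mathrm{Dirichlet}(\alpha_q)$ prior spans the full
catalogue, so coverage is approximate — the tests allow +/- 0.04. A
sparse truth distribution (e.g. $\mathrm{Dirichlet}(1/S)$) is *not* used
for this check: equal-tailed intervals have strictly positive lower
bounds and systematically miss contributions that are essentially zero,
a known property of equal-tailed intervals at a boundary rather than a
sampler defect. Permutation-test
type-I error and the Wald trend test are checked the same way (500 and
1000 null replicates).

## Numerical and degenerate-input choices

* Simplex draws are validated to 1e-12; EM stops at
  $\lVert\Delta\theta\rVert_\infty <$ 1e-8 (cap 10,000 iterations) and a
  decrease of the log-likelihood beyond 1e-9 aborts loudly.
* A single-source baseline gives the degenerate posterior $\theta = 1$
  with zero-width intervals and $\hat R = 1$.
* Permutation ties are counted as "at least as extreme" (with a 1e-12
  guard), making p-values conservative.
* First-occurrence ordering fixes haplotype IDs; frequencies are
  order-invariant.
* The merge resolves N-versus-base toward the base; base-versus-base
  conflicts always error.

## Known limitations

* MSA estimates population contributions; it never assigns an individual
  fin to a place, and the package deliberately offers no such function.
* Because the joint model updates baseline frequencies with
  mixture-assigned counts, a mixture much larger than the per-source
  baseline can "swamp" the baseline: the sampler finds a mode in which one
  source's frequency row is bent toward the mixture composition and that
  source absorbs most of the contribution. The EM cross-check (which holds
  q fixed) exposes this immediately. Keep baselines at least comparable in
  size to the mixture, or fix q by inflating `alpha_q`, when analyzing
  large market samples.
* With the sparse default contribution prior ($\alpha_\theta = 1/S$) the
  lower 95% bound of a weakly supported source collapses to numerical
  zero; detection of minor contributors is more stable under a flat
  contribution prior, at the cost of mildly inflated bounds for true
  zeros. The detection floor should sit above that inflation (1% of the
  market works well at the scales tested).
* The synthetic survey has no vendor-level correlation, so trend power in
  the real market will be lower than in simulations.
* Equivalence with any particular legacy MSA implementation is not
  claimed; the EM cross-check and closed-form diagnostics define
  correctness here.
* Genus-level trade records are tracked, not apportioned; if a species
  split is needed it must come from outside information.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` regenerates
the nine-source world, runs the full 4 x 100,000-iteration sampler, and
reports the maximum $\hat R$ together with the merged amplicon length;
`run_pipeline(default_scenario(seed))` executes all six stages end to end
and writes a manifest with per-stage record and exclusion tallies.
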