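---
title: "Methods: hurdle joint species distribution modelling of honey metagenomes"
author: "honeyJSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hurdle joint species distribution modelling of honey metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the filtering
rules, the model pair and its priors, the synthetic-data generator, the
numerical choices, and the places where the design was genuinely open and
a choice had to be made. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The data and the filtering chain

The observable is a genus × sample table of integer read counts from
shotgun-sequenced ("genome-skimmed") honey, annotated to genus, together
with the study design per sample — hive, beekeeper, site (with planar
coordinates), time point (June/July/August) and total reads — and a genus
trait table (taxonomic group; functional group such as nectar plant, bee
gut microbe, bee pathogen). A `HoneySkimExperiment` (a
`SummarizedExperiment` subclass) carries all three, plus an optional
blank-control count vector.

Filtering runs in a fixed order, each rule recorded in a filter log:

1. **Blank subtraction** (`subtractBlank`): reads seen in the no-template
   blank are treated as contamination and subtracted per genus from every
   sample, clamped at zero. The blank is applied uniformly to all samples
   because no per-sample scaling information exists for a single blank.
2. **Cellwise RRA threshold** (`filterRare`, stage 1): cells with
   within-sample relative read abundance strictly below 0.001% are
   zeroed. This targets tag jumping and misassignment, which produce
   trace counts.
3. **Mean-RRA inclusion** (stage 2): after recomputing RRA, genera whose
   unweighted mean RRA across samples is below 0.01% are dropped; exactly
   0.01% is retained. The mean is the per-sample mean of proportions, not
   a pooled-read ratio, so deep samples do not dominate the criterion.
   The cellwise rule is applied *before* the mean rule; the reverse order
   is defensible but changes which genera sit near the boundary, so the
   adopted order is logged with the run.
4. **Dominant-taxon removal** (`removeDominants`), for abundance
   analyses only: RRA is compositional, so a taxon surging to ~99% of a
   sample's reads (as *Apilactobacillus*, *Zygosaccharomyces* and AmFV
   can) depresses every other taxon's apparent abundance. Dropping the
   named taxa and renormalizing commutes with RRA computation on the
   subsetted counts (a tested invariant).
5. **Prevalence filter** (`prevalenceFilter`): genera present in fewer
   than 5% of samples are excluded from both model arms.

Removal thresholds are strict (`< 0.001%`, `< 5%`) and retention is
inclusive (`>= 0.01%`). Thresholds are user-facing in percent — the
field's notation — and held internally as proportions. The hurdle
response pairs `Y = (RRA > 0)` with `Z = log(RRA)` where present
(natural log; the base only rescales abundance coefficients).

## The model pair

Both arms share the design. Fixed effects: intercept, indicators for the
second and third time point (June is the reference), and log total reads
centred at its sample mean — the depth covariate absorbs technical
variation in sequencing effort. Genus coefficients are shrunk towards a
trait regression (intercept + one-hot taxonomic and functional groups),
so trait groups can share seasonal tendencies. Random effects are
latent-factor ("low-rank") terms for sample, site, hive and beekeeper:
factors vary over the units of a level, loadings over genera, and their
products add genus-specific random effects whose genus × genus outer
products encode residual associations. The site level is spatially
explicit: its factors get a unit-variance exponential-kernel Gaussian
prior `exp(-d / range)` over site coordinates. The sample-level term
exists to soak up residual genus-to-genus co-occurrence, not spatial
structure; predictions marginalize it.

The occurrence arm is a multivariate probit (residual variance fixed at
1, truncated-normal data augmentation). The abundance arm is Gaussian on
the observed (presence) cells only — "conditional on presence" defines
the support, so missing cells contribute nothing and are not imputed —
with a per-genus residual variance.

### Priors (implementation defaults)

The hyperparameters follow the conventions of hierarchical community
models; all are surfaced in `defaultPriors()` and none is load-bearing
for the package's checks:

* trait regression Γ: independent N(0, 10);
* coefficient covariance V: inverse-Wishart, df = p + 1, scale I;
* loadings: multiplicative-gamma shrinkage (local t-prior df ν = 3,
  column-multiplier shapes a₁ = 2, a₂ = 3), with a fixed maximum of
  `nFactors` factors per level (default 3; the desk-scale tests use 2);
* residual variance σ²ⱼ: inverse-gamma(2, 1);
* spatial range: a discrete grid of 21 values from 0 to the maximum
  inter-site distance, with half the prior mass on 0 (no spatial
  structure) — a non-spatial site level is also available via
  `spatialSite = FALSE`.

### The Gibbs sweep

Update order is fixed: (1) truncated-normal liabilities (probit arm);
(2) genus coefficients — for the probit arm all genera share one
posterior precision, solved with a single Cholesky; (3) trait regression
Γ; (4) coefficient covariance V; (5) per random level: latent factors
(units with equal effective weight are batched; the spatial level is
sampled jointly across units and factors, followed by a grid-Gibbs step
for the range, whose per-grid-point kernel Cholesky factors are
precomputed once), then loadings, then shrinkage parameters; (6)
residual variances (Gaussian arm). Chains are independent, seeded
`seed + chain - 1`, so a fixed seed and schedule reproduce every draw
bit for bit.

`McmcSchedule` holds chains/iterations/burn-in/thinning;
`retainedDraws()` gives `floor((iterations - burnin)/thin)` per chain.
The canonical long schedule of 4 chains × 375,000 iterations with
125,000 burn-in and thinning 1,000 retains 250 draws per chain, 1,000
total; the package's tests run desk-scale schedules (2–4 chains of
1,500–4,000 iterations on 20–40 genera × 100–150 samples), sizes chosen
so the full suite completes in minutes while leaving the recovery
margins wide.

Convergence is monitored with the classic Gelman–Rubin PSRF
(between/within-chain variance ratio), computed per genus coefficient.

## Identifiability: what is compared, and why

Two non-identifiabilities shape every check in this package.

* **Rotation/scale of latent factors.** Loadings and factors are only
  identified up to rotations (and compensating rescalings). Tests and
  summaries therefore only use identified functionals: linear
  predictors, predictions, and variance contributions. The
  variance-partition contribution of a level is the genus's squared
  loadings summed with each factor weighted by its empirical second
  moment over units — invariant under `λ → cλ, η → η/c`, and a tested
  property.
* **Compositionality of RRA.** Log RRA equals the log abundance weight
  minus the log per-sample weight sum; the latter is common to all
  genera in the sample, so a per-season constant is absorbed into every
  genus's abundance coefficients. Only genus-centred contrasts of
  abundance coefficients are identified, and recovery coverage is
  evaluated on them (`centredBetaIntervals`). The occurrence arm has no
  such normalizer and its coefficients are compared directly.

## Post-fit statistics

* **Variance partition**: per draw, the variance over samples of the
  time block and the depth block of the fixed part, plus each random
  level's contribution, normalized to fractions (they sum to 1 by
  construction) and averaged over draws; group summaries average genus
  fractions within taxonomic and functional groups, in percent.
* **Fit metrics**: Tjur *R*² (mean predicted probability over presences
  minus absences), AUC (mid-rank Mann–Whitney; ties count half), and the
  squared Pearson correlation between observed and predicted log
  abundance over presence cells. One-class genera are flagged `NA` and
  excluded from group averages with a logged count.
* **Explanatory vs predictive power**: explanatory predictions condition
  on the estimated latent factors; predictive power uses twofold
  cross-validation with *samples* as the randomized units (the natural
  reading for honey samples; hive-level blocking would test a different,
  harsher generalization and is left to the user via the folds). For
  held-out samples, factors of units unseen in training are integrated
  out analytically — for the probit arm by liability-variance inflation,
  `pnorm(mu / sqrt(1 + sum(lambda^2)))` — and the sample level is always
  marginalized. Because sample-level factors absorb residual
  co-occurrence, they raise explanatory but not predictive power; the
  package's null-simulation check (predictive Tjur *R*² centred on zero
  without signal) and the explanatory ≥ predictive comparison make that
  gap visible.
* **Seasonal trends**: occurrence probabilities per time point from the
  fixed part only, with the depth covariate at its sample mean (its
  centred value 0), for every draw. `pIncrease` is the posterior
  probability that the August probability exceeds June's; exact ties
  count one half (so a degenerate zero August effect yields 0.5, "no
  trend", rather than an artefactual call). Calls use the symmetric 95%
  rule: increase at ≥ 0.95, decrease at ≤ 0.05.
* **Temporal co-occurrence Ω**: per draw,
  `Omega = outer(betaT2, betaT2) + outer(betaT3, betaT3)`; the posterior
  mean, elementwise sign probabilities, and sign calls at the 90% rule.
  The diagonal is a sum of squares, hence nonnegative in every draw; the
  vectorized path is tested to 1e-12 against a brute-force loop over
  pairs and draws.
* **Hurdle combination**: the arms are fitted separately but predict
  together; the unconditional expected RRA is
  `P(presence) * exp(mu + sigma2/2)` (`expectedAbundance`), while *R*²
  is evaluated on conditional presence-only predictions, matching the
  model's definition. Both conventions are exposed.

## The synthetic-data generator

`simulateHoneyData()` draws from the exact generative structure the
model assumes, so every downstream stage can be tested against known
truth: a realized design (default 14 beekeepers, 41 hives on 30 sites,
three time points, 7% missingness — the study scale of ~115 realized
samples; dropout concentrated in July surveys is not modelled, only
uniform missingness, since no rate per time point is available),
log-normal depths (median 2 × 10⁷ genus-assigned reads, log-sd 0.5),
trait-linked coefficients (group mean plus genus noise), latent factors
per level with chosen scales (zero switches a level off; the site level
draws from the exponential kernel, range 3 on a 10 × 10 arena),
Bernoulli-probit occurrence, log-normal weights, per-sample multinomial
allocation of the drawn depth over `weight × presence` (the analysis
only ever observes RRA, so no count-generation law is dictated by it;
multinomial allocation is the simplest mechanism producing
compositional, depth-dependent integer counts), multiplicative
dominance spikes (factor 2,000 in 10% of samples for up to three genera,
reproducing ~99% single-taxon dominance), and Poisson blank
contamination for a handful of genera. A sample in which no genus occurs
has its most probable genus forced present so the depth can be
allocated; at realistic prevalences this is a vanishing-probability
repair.

What the generator deliberately does **not** emulate: taxonomic
misassignment structure (contamination is independent Poisson, not
phylogenetically clustered), overdispersion beyond the multinomial,
correlated occurrence–abundance noise within a cell, and seasonal
depth confounding. Passing recovery tests on this generator therefore
shows the estimator is correct *under the model's own assumptions* —
not that real honey skims satisfy them.

## Numerical choices and degenerate inputs

* Truncated-normal draws clamp the uniform deviate to
  `[1e-12, 1 - 1e-12]` to avoid infinite liabilities in saturated cells.
* Kernel matrices get a `1e-8` diagonal jitter before Cholesky.
* An all-zero sample column is an error naming the sample (RRA
  undefined); a genus with fewer than two observed abundance cells is
  rejected with advice to exclude it; non-binary occurrence input,
  rank-deficient fixed designs, unknown dominant ids, negative blanks
  and malformed count tables (duplicate ids, non-integer cells, empty
  files) all fail fast with informative messages.
* `retainedDraws` floors the per-chain count; a burn-in not smaller than
  the iteration count is a validity error.
* AUC ties: mid-rank convention (ties count one half), matching the
  brute-force pair enumeration exactly.

## Known limitations

* The sampler is statistically, not bitwise, comparable to other
  implementations of this model family; equivalence is checked against
  analytic conditionals, numerical integration, and ground-truth
  recovery, never draw-for-draw.
* Grid sampling of the spatial range trades resolution for robustness;
  ranges between grid points are not visited.
* Cross-validation refits per fold at the configured schedule; with very
  short schedules the predictive metrics inherit Monte-Carlo noise.
* No phylogenetic correlation structure among genera is implemented
  (none is used in the target analysis), and aggregation above genus
  level is out of scope: inputs are already genus-level tables.
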