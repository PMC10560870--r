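# honeyJSDM

Honey is a biological archive: shotgun sequencing of its residual DNA
("genome skimming") recovers the plants a colony foraged on and the
bacteria, fungi and viruses the bees carried home, hive by hive and month
by month. `honeyJSDM` provides a tested, reusable pipeline for asking how
strongly the *season* shapes this interaction community relative to the
imprints of the *site*, the *hive*, the *beekeeper* and the individual
*sample* — the typical crossed design of an apiary survey (tens of
beekeepers, ~40 hives on ~30 sites, sampled in June, July and August).

It is aimed at molecular ecologists working with genus-level count tables
from annotated honey (or other diet/microbiome) skims, and implements:

* **RRA filtering.** Blank-control subtraction; zeroing of cells with
  within-sample relative read abundance (RRA) < 0.001%; removal of genera
  with mean RRA < 0.01%; optional removal of dominant taxa (e.g.
  *Apilactobacillus*, *Zygosaccharomyces*, AmFV, which can reach ~99% of
  a sample's reads) with renormalization; a 5% prevalence filter before
  modelling.
* **A hurdle pair of Bayesian joint species distribution models.**
  Presence–absence by multivariate probit and log-RRA conditional on
  presence by a log-normal model, sharing one design: fixed effects for
  sampling period (June as reference) and log total reads, genus-level
  trait effects (taxonomic and functional group), and crossed
  latent-factor random effects for sample, site (spatially explicit,
  exponential kernel), hive and beekeeper, fitted by a Gibbs sampler
  written for exactly this structure.
* **Post-fit statistics.** Gelman–Rubin PSRF; variance partitioning over
  fixed blocks and random levels; Tjur *R*², AUC and linear *R*² for
  explanatory and (twofold cross-validated) predictive power;
  fixed-effect seasonal occurrence predictions with 95%-posterior trend
  calls; and the temporal co-occurrence matrix
  **Ω**, with Ω<sub>j1,j2</sub> = β<sub>T2,j1</sub>β<sub>T2,j2</sub> +
  β<sub>T3,j1</sub>β<sub>T3,j2</sub> and 90%-posterior sign calls.
* **A synthetic-data generator** with known ground truth that emulates
  the hierarchical design, log-normal sequencing depths, hurdle zero
  inflation, trait-linked seasonal responses, single-taxon dominance
  spikes and blank contamination — so the whole pipeline is testable
  without any sequence download.

## Model

For genus *j* in sample *i*, with fixed design
**x**<sub>i</sub> = (1, T2<sub>i</sub>, T3<sub>i</sub>, log reads<sub>i</sub>):

* occurrence: *y*<sub>ij</sub> ~ Bernoulli(Φ(**x**<sub>i</sub>ᵀ**β**<sub>j</sub> + Σ<sub>ℓ</sub> **η**<sup>(ℓ)</sup><sub>u(i)</sub>ᵀ**λ**<sup>(ℓ)</sup><sub>j</sub>))
* abundance | presence: log RRA<sub>ij</sub> ~ N(**x**<sub>i</sub>ᵀ**β̃**<sub>j</sub> + Σ<sub>ℓ</sub> …, σ²<sub>j</sub>)

with genus coefficients shrunk towards a trait regression,
**β**<sub>j</sub> ~ N(Γᵀ**t**<sub>j</sub>, V), latent factors
**η**<sup>(ℓ)</sup> per unit of each random level ℓ (the site level gets
an exponential spatial prior over site coordinates) and
multiplicative-gamma shrinkage on the loadings. See the methods vignette
(`vignettes/honeyJSDM-methods.Rmd`) for priors, update order and design
choices.

## Worked example

```r
library(honeyJSDM)

x <- simulateHoneyData(nGenera = 40, seed = 1)   # study-scale synthetic data
x
#> HoneySkimExperiment: 40 genera x 119 samples
#>   timepoints: June, July, August
#>   design: 14 beekeepers, 41 hives, 30 sites
#>   synthetic: generating truth attached

pp <- preprocessPipeline(x)                      # blank, RRA filters, hurdle
pp$response
#> HurdleResponse: 40 genera x 119 samples
#>   prevalence: median 0.50 (range 0.18-0.75)
#>   observed abundance cells: 2333

sched <- McmcSchedule(nChains = 2, nIterations = 1500, nBurnin = 500, thin = 2)
tf <- traitFrame(x); traits <- data.frame(genus = rownames(tf), tf)
fo <- fitOccurrence(pp$response, schedule = sched, seed = 1,
                    traits = traits, nFactors = 2)
fa <- fitAbundance(pp$response, schedule = sched, seed = 2,
                   traits = traits, nFactors = 2)   # a few minutes together
max(psrf(fo))
#> [1] 1.07

variancePartition(fo, traits)
#> VariancePartition over 40 genera
#>   mean % of variance:
#>     time          19.5
#>     total_reads    9.4
#>     sample        28.8
#>     site          14.3
#>     hive          12.7
#>     beekeeper     15.3

met <- fitMetrics(fo, fa, pp$response)
round(sapply(met[-1], mean, na.rm = TRUE), 2)
#> tjurR2    auc     r2
#>   0.35   0.90   0.87

predictSeasonal(fo)
#> SeasonalPrediction for 40 genera (95% rule):
#>   increase 16, decrease 8, none 16

omegaMatrix(fo)
#> OmegaSummary: 40 genera, 780 pairs (90% rule)
#>   sign calls: 236 positive, 170 negative
```

Reading the output: `time` at 19.5% says the season explains about a
fifth of the (explained) variation in genus occurrence for this synthetic
community, against the sample/site/hive/beekeeper levels; the generator
planted strong trait-linked seasonal responses, and the trend and Ω calls
recover which genera rise towards August and which pairs share seasonal
timing. On real data the same calls feed directly into tables of
seasonally increasing/decreasing genera and a co-occurrence edge list
(`runPipeline()` writes all of these as CSV/TSV).

A one-call version of the above, from a YAML config with filter
thresholds, model block, MCMC schedule and seeds, is

```r
runPipeline("config.yaml")   # simulate/load -> preprocess -> fit -> postfit -> report
```

and `inst/scripts/run_pipeline.R` wraps it for the shell.

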