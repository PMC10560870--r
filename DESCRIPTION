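Package: honeyJSDM
Title: Hurdle Joint Species Distribution Modelling of Honey Metagenome Genus Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing seasonal and management imprints on the
    interaction partners of honeybees as archived in the DNA content of honey.
    Implements relative-read-abundance (RRA) filtering of genus-level
    genome-skimming count tables (blank subtraction, cellwise and mean-RRA
    thresholds, dominant-taxon removal, prevalence filtering), a hurdle pair of
    Bayesian joint species distribution models (probit occurrence and log-normal
    abundance conditional on presence) with season and sequencing-depth fixed
    effects, genus-level trait effects, and crossed latent-factor random effects
    for sample, site (spatially explicit), hive and beekeeper, fitted by Gibbs
    sampling. Post-fit summaries include variance partitioning, Tjur R2, AUC and
    linear R2 for explanatory and cross-validated predictive power, fixed-effect
    seasonal occurrence predictions with posterior trend classification, and the
    temporal co-occurrence matrix Omega with posterior sign probabilities. A
    synthetic-data generator with known ground truth emulates the hierarchical
    study design (beekeepers, hives, sites, time points), sequencing-depth
    variation, zero inflation, trait-linked seasonal responses, single-taxon
    dominance and blank contamination, so the full pipeline is testable without
    access to raw sequence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
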