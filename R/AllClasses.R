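#' @import methods
#' @importFrom stats rnorm runif rgamma rpois rmultinom rWishart pnorm qnorm
#'   dnorm var cor sd rlnorm rbinom quantile setNames median dist
#'   model.matrix as.formula
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData rowData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Container for a genus-by-sample honey genome-skimming count table
#'
#' `HoneySkimExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] and holds an integer read
#' count matrix (genera as rows, samples as columns) together with the study
#' design per sample (`colData`: hive, beekeeper, site with planar
#' coordinates, time point, total reads) and genus-level traits (`rowData`:
#' taxonomic group, functional group). An optional blank-control count vector
#' and, for synthetic data, the generating ground truth are kept in
#' `metadata()`.
#'
#' @seealso [HoneySkimExperiment()] for the constructor,
#'   [countsMatrix()], [sampleFrame()], [traitFrame()] for accessors.
#' @export
setClass("HoneySkimExperiment", contains = "SummarizedExperiment")

.requiredSampleCols <- c("sample", "hive", "beekeeper", "site",
                         "siteX", "siteY", "timepoint", "totalReads")

setValidity("HoneySkimExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts must not contain NA")
    else if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    else if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "genus ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.requiredSampleCols, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing sample columns: ",
                         paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(cd)) {
    # each hive belongs to exactly one beekeeper and one site
    hb <- unique(data.frame(h = cd$hive, b = cd$beekeeper, s = cd$site))
    if (anyDuplicated(hb$h))
      msg <- c(msg, "each hive must map to exactly one beekeeper and one site")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HoneySkimExperiment
#'
#' @param counts integer matrix, genera as rows and samples as columns, with
#'   row and column names.
#' @param samples `data.frame` with one row per sample (matched to count
#'   columns by the `sample` column or by order) holding `sample`, `hive`,
#'   `beekeeper`, `site`, `siteX`, `siteY`, `timepoint`, `totalReads`.
#' @param traits optional `data.frame` keyed by genus with columns
#'   `taxonomicGroup` and `functionalGroup`.
#' @param blank optional named nonnegative integer vector of blank-control
#'   counts per genus.
#' @param truth optional list of generating parameters (synthetic data only).
#' @return A [HoneySkimExperiment-class] object.
#' @export
HoneySkimExperiment <- function(counts, samples, traits = NULL, blank = NULL,
                                truth = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.null(samples$sample)) {
    if (!all(colnames(counts) %in% samples$sample))
      stop("count columns missing from sample table: ",
           paste(setdiff(colnames(counts), samples$sample), collapse = ", "))
    samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  } else {
    samples$sample <- colnames(counts)
  }
  rownames(samples) <- samples$sample
  rd <- NULL
  if (!is.null(traits)) {
    key <- if (!is.null(traits$genus)) traits$genus else rownames(traits)
    if (!all(rownames(counts) %in% key))
      stop("trait table does not cover all genera")
    rd <- S4Vectors::DataFrame(traits[match(rownames(counts), key), ,
                                      drop = FALSE])
    rownames(rd) <- rownames(counts)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(samples))
  if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
  md <- list()
  if (!is.null(blank)) {
    if (any(blank < 0)) stop("blank counts must be nonnegative")
    md$blank <- blank
  }
  if (!is.null(truth)) md$truth <- truth
  S4Vectors::metadata(se) <- md
  new("HoneySkimExperiment", se)
}

#' Hurdle response matrices for the joint model pair
#'
#' Pairs the binary occurrence matrix `Y` with the log-RRA-given-presence
#' matrix `Z` (`NA` exactly where a genus is absent), plus the per-sample log
#' total reads used as the sequencing-effort covariate.
#'
#' @slot Y genus x sample binary matrix.
#' @slot Z genus x sample numeric matrix, `NA` where `Y == 0`.
#' @slot logTotalReads numeric, per sample.
#' @slot samples data.frame of per-sample design variables.
#' @export
setClass("HurdleResponse",
         representation(Y = "matrix", Z = "matrix",
                        logTotalReads = "numeric", samples = "data.frame"))

setValidity("HurdleResponse", function(object) {
  msg <- character()
  if (!identical(dim(object@Y), dim(object@Z)))
    msg <- c(msg, "Y and Z must have identical dimensions")
  if (!all(object@Y %in% c(0, 1)))
    msg <- c(msg, "Y must be binary")
  if (identical(dim(object@Y), dim(object@Z))) {
    if (any(is.na(object@Z) != (object@Y == 0)))
      msg <- c(msg, "Z must be defined exactly where Y == 1")
  }
  if (length(object@logTotalReads) != ncol(object@Y))
    msg <- c(msg, "logTotalReads must have one entry per sample")
  if (any(!is.finite(object@logTotalReads)))
    msg <- c(msg, "logTotalReads must be finite")
  if (length(msg)) msg else TRUE
})

#' MCMC schedule for the Gibbs samplers
#'
#' @slot nChains number of independent chains.
#' @slot nIterations sweeps per chain (including burn-in).
#' @slot nBurnin initial sweeps discarded per chain.
#' @slot thin keep every `thin`-th post-burn-in sweep.
#' @seealso [retainedDraws()]
#' @export
setClass("McmcSchedule",
         representation(nChains = "integer", nIterations = "integer",
                        nBurnin = "integer", thin = "integer"))

setValidity("McmcSchedule", function(object) {
  msg <- character()
  if (object@nBurnin >= object@nIterations)
    msg <- c(msg, "burn-in must be smaller than the number of iterations")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@nChains < 1L) msg <- c(msg, "need at least one chain")
  if (length(msg)) msg else TRUE
})

#' @param nChains,nIterations,nBurnin,thin see the class slots.
#' @rdname McmcSchedule-class
#' @export
McmcSchedule <- function(nChains = 4, nIterations = 3000, nBurnin = 1000,
                         thin = 4) {
  new("McmcSchedule", nChains = as.integer(nChains),
      nIterations = as.integer(nIterations),
      nBurnin = as.integer(nBurnin), thin = as.integer(thin))
}

#' Model specification for one arm of the hurdle pair
#'
#' Holds the per-sample fixed-effect design (intercept, July and August
#' indicators with June as the reference, centred log total reads), the
#' per-genus trait design, the crossed random-level descriptors (sample,
#' site, hive, beekeeper; the site level carries coordinates and an
#' exponential spatial kernel), and the prior hyperparameters.
#'
#' @slot X sample x predictor fixed-effect design matrix.
#' @slot fixedBlocks named list mapping variance-partition blocks ("time",
#'   "total_reads") to columns of `X`.
#' @slot traitDesign genus x trait-predictor design matrix.
#' @slot randomLevels list of level descriptors: `name`, `units` (factor per
#'   sample), `nFactors`, `spatial`, `coords`.
#' @slot priors list of hyperparameters (see [defaultPriors()]).
#' @slot genusNames character.
#' @export
setClass("HurdleModelSpec",
         representation(X = "matrix", fixedBlocks = "list",
                        traitDesign = "matrix", randomLevels = "list",
                        priors = "list", genusNames = "character"))

#' Posterior draws from one fitted hurdle-model arm
#'
#' @slot family "probit" (occurrence) or "gaussian" (log-abundance given
#'   presence).
#' @slot beta predictor x genus x draw array of genus coefficients.
#' @slot gamma trait-predictor x predictor x draw array (trait regression).
#' @slot V predictor x predictor x draw array (coefficient covariance).
#' @slot sigma2 genus x draw matrix of residual variances (gaussian arm only).
#' @slot lambda per random level, a factor x genus x draw loading array.
#' @slot eta per random level, a unit x factor x draw latent-factor array.
#' @slot alpha per spatial level, spatial-range draws.
#' @slot chain chain index per retained draw.
#' @slot spec the [HurdleModelSpec-class] used.
#' @slot schedule the [McmcSchedule-class] used.
#' @export
setClass("HurdleFit",
         representation(family = "character", beta = "array",
                        gamma = "array", V = "array", sigma2 = "matrix",
                        lambda = "list", eta = "list", alpha = "list",
                        chain = "integer", spec = "HurdleModelSpec",
                        schedule = "McmcSchedule"))

#' Variance partition over fixed blocks and random levels
#'
#' @slot fractions genus x component matrix of variance fractions (rows sum
#'   to 1).
#' @slot groupMeans named list of component x group matrices averaged within
#'   taxonomic / functional groups (percent).
#' @export
setClass("VariancePartition",
         representation(fractions = "matrix", groupMeans = "list"))

#' Fixed-effect seasonal occurrence predictions with trend calls
#'
#' @slot occProb draw x genus x timepoint array of occurrence probabilities.
#' @slot probMean genus x timepoint posterior means.
#' @slot pIncrease per genus, posterior probability that the August
#'   occurrence probability exceeds the June one.
#' @slot trendCall "increase", "decrease" or "none" at the threshold.
#' @slot threshold posterior-probability threshold for a directional call.
#' @export
setClass("SeasonalPrediction",
         representation(occProb = "array", probMean = "matrix",
                        pIncrease = "numeric", trendCall = "character",
                        threshold = "numeric"))

#' Posterior summary of the temporal co-occurrence matrix Omega
#'
#' @slot omegaMean genus x genus posterior mean.
#' @slot pPos,pNeg posterior probabilities that each element is positive /
#'   negative.
#' @slot signCall -1, 0 or +1 at the threshold.
#' @slot threshold posterior-probability threshold for a sign call.
#' @export
setClass("OmegaSummary",
         representation(omegaMean = "matrix", pPos = "matrix",
                        pNeg = "matrix", signCall = "matrix",
                        threshold = "numeric"))
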