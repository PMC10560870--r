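## File formats, configuration, and the end-to-end pipeline runner.
## Count tables travel as TSV (genera as rows, samples as columns),
## metadata and traits as CSV, the generating truth and logs as JSON.

#' Read a genus count table from TSV
#'
#' Expects a header row of sample ids and a first column of genus ids.
#' Duplicate ids, non-integer or negative cells and empty files are
#' rejected with informative errors.
#'
#' @param path TSV file path.
#' @return genus x sample numeric matrix.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty count table: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a genus column and >= 1 sample")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate genus id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample id(s)")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    badRow <- which(is.na(suppressWarnings(
      as.numeric(df[[bad + 1]]))))[1]
    stop("non-numeric cell in column '", colnames(df)[bad + 1],
         "' at line ", badRow + 1L)
  }
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    stop("invalid count (negative, missing or non-integer) at line ",
         bad[1] + 1L, ", sample '", colnames(m)[bad[2]], "'")
  }
  rownames(m) <- ids
  m
}

#' Write a genus count table as TSV
#'
#' @param counts genus x sample matrix.
#' @param path output path.
#' @export
writeCountTable <- function(counts, path) {
  df <- data.frame(genus = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a full dataset to a directory
#'
#' Counts as TSV, sample metadata and traits as CSV, blank vector as CSV,
#' generating truth (when present) as a JSON sidecar.
#'
#' @param x a [HoneySkimExperiment-class].
#' @param dir output directory (created if needed).
#' @return `writeDataset`: the directory, invisibly. `readDataset`: a
#'   [HoneySkimExperiment-class] (without truth; truth is a generator-side
#'   record).
#' @export
writeDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountTable(countsMatrix(x), file.path(dir, "counts.tsv"))
  write.csv(sampleFrame(x), file.path(dir, "samples.csv"),
            row.names = FALSE)
  tf <- traitFrame(x)
  if (ncol(tf))
    write.csv(data.frame(genus = rownames(tf), tf, check.names = FALSE),
              file.path(dir, "traits.csv"), row.names = FALSE)
  bl <- blankCounts(x)
  if (!is.null(bl))
    write.csv(data.frame(genus = names(bl), count = as.numeric(bl)),
              file.path(dir, "blank.csv"), row.names = FALSE)
  tr <- truthParams(x)
  if (!is.null(tr)) {
    slim <- tr[c("betaOcc", "betaAbund", "sigma2Beta", "levelScales",
                 "spatialRange", "sigma2Resid")]
    jsonlite::write_json(slim, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(dir)
}

#' @rdname writeDataset
#' @param dir directory holding `counts.tsv`, `samples.csv` and optional
#'   `traits.csv` / `blank.csv`.
#' @export
readDataset <- function(dir) {
  counts <- readCountTable(file.path(dir, "counts.tsv"))
  samples <- read.csv(file.path(dir, "samples.csv"),
                      stringsAsFactors = FALSE)
  samples$timepoint <- factor(samples$timepoint,
                              levels = unique(samples$timepoint))
  traits <- NULL
  tp <- file.path(dir, "traits.csv")
  if (file.exists(tp)) traits <- read.csv(tp, stringsAsFactors = FALSE)
  blank <- NULL
  bp <- file.path(dir, "blank.csv")
  if (file.exists(bp)) {
    b <- read.csv(bp, stringsAsFactors = FALSE)
    blank <- setNames(b$count, b$genus)
  }
  HoneySkimExperiment(counts, samples, traits = traits, blank = blank)
}

#' Read and validate a pipeline configuration
#'
#' YAML (or an equivalent list) with blocks `simulate` or `paths`,
#' `filters`, `model`, `mcmc`, `seed`, `outputDir`. Validation is
#' pre-flight: thresholds must lie in [0, 100] percent and referenced
#' files must exist before any compute starts.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg$filters <- utils::modifyList(
    list(cellPct = 0.001, meanPct = 0.01, minPrevalence = 0.05,
         dominants = NULL), cfg$filters %||% list())
  cfg$model <- utils::modifyList(
    list(randomLevels = c("sample", "site", "hive", "beekeeper"),
         nFactors = 2, spatialSite = TRUE), cfg$model %||% list())
  cfg$mcmc <- utils::modifyList(
    list(nChains = 2, nIterations = 1500, nBurnin = 500, thin = 2),
    cfg$mcmc %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$outputDir)) stop("config must set outputDir")
  with(cfg$filters, {
    if (cellPct < 0 || cellPct > 100 || meanPct < 0 || meanPct > 100)
      stop("RRA thresholds must lie in [0, 100] percent")
    if (minPrevalence < 0 || minPrevalence > 1)
      stop("minPrevalence must lie in [0, 1]")
  })
  if (is.null(cfg$simulate)) {
    for (p in unlist(cfg$paths[c("counts", "samples")]))
      if (!file.exists(p)) stop("missing input file: ", p)
    for (nm in c("traits", "blank"))
      if (!is.null(cfg$paths[[nm]]) && !file.exists(cfg$paths[[nm]]))
        stop("missing input file: ", cfg$paths[[nm]])
  }
  cfg
}

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline from a configuration
#'
#' Stages in order: simulate (or load), preprocess (blank subtraction,
#' rare-taxon filters, optional dominant removal, hurdle construction,
#' prevalence filter), fit (both hurdle arms), postfit (convergence
#' report, variance partitions, explanatory metrics, seasonal trend
#' calls, Omega), report (tables plus a run manifest with the config
#' hash). Rerunning with the same config reproduces all outputs.
#'
#' @param config path to a YAML config or a list (see
#'   [readPipelineConfig()]).
#' @return invisibly, a list with the main result objects and the output
#'   directory.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  out <- cfg$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    r
  }
  x <- stage("simulate/load", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      simulateHoneyData(nGenera = sim$nGenera %||% 40,
                        spec = do.call(designSpec, sim$design %||% list()),
                        seed = as.integer(sim$seed %||% cfg$seed))
    } else {
      counts <- readCountTable(cfg$paths$counts)
      samples <- read.csv(cfg$paths$samples, stringsAsFactors = FALSE)
      samples$timepoint <- factor(samples$timepoint,
                                  levels = unique(samples$timepoint))
      traits <- if (!is.null(cfg$paths$traits))
        read.csv(cfg$paths$traits, stringsAsFactors = FALSE)
      blank <- if (!is.null(cfg$paths$blank)) {
        b <- read.csv(cfg$paths$blank, stringsAsFactors = FALSE)
        setNames(b$count, b$genus)
      }
      HoneySkimExperiment(counts, samples, traits = traits, blank = blank)
    }
  })
  pp <- stage("preprocess", {
    r <- preprocessPipeline(x, cellPct = cfg$filters$cellPct,
                            meanPct = cfg$filters$meanPct,
                            minPrevalence = cfg$filters$minPrevalence,
                            dominantIds = cfg$filters$dominants)
    jsonlite::write_json(r$log, file.path(out, "filter_log.json"),
                         auto_unbox = TRUE, digits = NA)
    r
  })
  traits <- traitFrame(x)
  traits <- if (ncol(traits))
    data.frame(genus = rownames(traits), traits) else NULL
  sched <- do.call(McmcSchedule, cfg$mcmc)
  fits <- stage("fit", {
    fo <- fitOccurrence(pp$response, schedule = sched, seed = cfg$seed,
                        traits = traits,
                        randomLevels = cfg$model$randomLevels,
                        nFactors = cfg$model$nFactors,
                        spatialSite = cfg$model$spatialSite)
    fa <- fitAbundance(pp$response, schedule = sched,
                       seed = cfg$seed + 100L, traits = traits,
                       randomLevels = cfg$model$randomLevels,
                       nFactors = cfg$model$nFactors,
                       spatialSite = cfg$model$spatialSite)
    saveRDS(list(occurrence = fo, abundance = fa),
            file.path(out, "fits.rds"))
    list(occ = fo, ab = fa)
  })
  res <- stage("postfit", {
    conv <- data.frame(model = c("occurrence", "abundance"),
                       maxBetaPsrf = c(max(psrf(fits$occ)),
                                       max(psrf(fits$ab))))
    write.csv(conv, file.path(out, "convergence.csv"), row.names = FALSE)
    vpO <- variancePartition(fits$occ, traits)
    vpA <- variancePartition(fits$ab, traits)
    writeVariancePartition(vpO, file.path(out, "varpart_occurrence.csv"))
    writeVariancePartition(vpA, file.path(out, "varpart_abundance.csv"))
    met <- fitMetrics(fits$occ, fits$ab, pp$response)
    write.csv(met, file.path(out, "fit_metrics.csv"), row.names = FALSE)
    sp <- predictSeasonal(fits$occ)
    write.csv(data.frame(genus = names(sp@pIncrease),
                         pIncrease = sp@pIncrease,
                         trend = sp@trendCall),
              file.path(out, "seasonal_trends.csv"), row.names = FALSE)
    om <- omegaMatrix(fits$occ)
    write.table(om@omegaMean, file.path(out, "omega_mean.tsv"),
                sep = "\t", quote = FALSE)
    writeOmegaEdges(om, file.path(out, "omega_edges.csv"))
    list(varpartOcc = vpO, varpartAb = vpA, metrics = met,
         seasonal = sp, omega = om, convergence = conv)
  })
  stage("report", {
    manifest <- list(configHash = .configHash(cfg), seed = cfg$seed,
                     package = as.character(packageVersion("honeyJSDM")),
                     rVersion = R.version.string,
                     generaModelled = nrow(pp$response@Y),
                     samples = ncol(pp$response@Y),
                     retainedDraws = retainedDraws(sched))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(list(data = x, preprocess = pp, fits = fits, results = res,
                 outputDir = out))
}

#' Write a variance partition as a components x groups CSV
#'
#' Rows are components (time, total reads, random levels), columns the
#' overall mean plus taxonomic and functional group means, in percent.
#'
#' @param vp a [VariancePartition-class].
#' @param path output CSV.
#' @export
writeVariancePartition <- function(vp, path) {
  tab <- data.frame(component = colnames(vp@fractions),
                    Total = 100 * colMeans(vp@fractions))
  for (gm in vp@groupMeans)
    tab <- cbind(tab, t(gm))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write Omega sign calls as an edge list
#'
#' @param om an [OmegaSummary-class].
#' @param path output CSV.
#' @export
writeOmegaEdges <- function(om, path) {
  idx <- which(upper.tri(om@signCall) & om@signCall != 0, arr.ind = TRUE)
  edges <- data.frame(genus1 = rownames(om@signCall)[idx[, 1]],
                      genus2 = colnames(om@signCall)[idx[, 2]],
                      sign = om@signCall[idx],
                      omegaMean = om@omegaMean[idx],
                      pSupport = pmax(om@pPos[idx], om@pNeg[idx]))
  write.csv(edges, path, row.names = FALSE)
  invisible(path)
}
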