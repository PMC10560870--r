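#' Accessors for HoneySkimExperiment
#'
#' `countsMatrix()` returns the genus x sample read-count matrix,
#' `rraMatrix()` the relative-read-abundance assay (computing it on the fly
#' if absent), `sampleFrame()` the per-sample design table, `traitFrame()`
#' the genus trait table and `blankCounts()` the blank-control vector.
#'
#' @param x a [HoneySkimExperiment-class].
#' @return A matrix or data.frame as described.
#' @name accessors
NULL

#' @rdname accessors
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname accessors
#' @export
rraMatrix <- function(x) {
  if ("rra" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "rra")
  else
    .rraFromCounts(countsMatrix(x))
}

#' @rdname accessors
#' @export
sampleFrame <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @rdname accessors
#' @export
traitFrame <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname accessors
#' @export
blankCounts <- function(x) S4Vectors::metadata(x)$blank

#' @rdname accessors
#' @export
truthParams <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn HoneySkimExperiment-class compact display.
#' @param object a `HoneySkimExperiment`.
#' @export
setMethod("show", "HoneySkimExperiment", function(object) {
  cat("HoneySkimExperiment:", nrow(object), "genera x", ncol(object),
      "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  timepoints:", paste(levels(factor(cd$timepoint)), collapse = ", "),
      "\n")
  cat("  design:", length(unique(cd$beekeeper)), "beekeepers,",
      length(unique(cd$hive)), "hives,", length(unique(cd$site)), "sites\n")
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  synthetic: generating truth attached\n")
  invisible(NULL)
})

#' @describeIn HurdleResponse-class compact display.
#' @param object a `HurdleResponse`.
#' @export
setMethod("show", "HurdleResponse", function(object) {
  prev <- rowMeans(object@Y)
  cat("HurdleResponse:", nrow(object@Y), "genera x", ncol(object@Y),
      "samples\n")
  cat(sprintf("  prevalence: median %.2f (range %.2f-%.2f)\n",
              median(prev), min(prev), max(prev)))
  cat(sprintf("  observed abundance cells: %d\n", sum(object@Y == 1)))
  invisible(NULL)
})

#' @describeIn HurdleFit-class compact display.
#' @param object a `HurdleFit`.
#' @export
setMethod("show", "HurdleFit", function(object) {
  d <- dim(object@beta)
  cat(sprintf("HurdleFit (%s): %d genera, %d predictors, %d draws (%d chains)\n",
              object@family, d[2], d[1], d[3],
              length(unique(object@chain))))
  if (length(object@lambda))
    cat("  random levels:",
        paste(names(object@lambda), collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn VariancePartition-class compact display.
#' @param object a `VariancePartition`.
#' @export
setMethod("show", "VariancePartition", function(object) {
  cat("VariancePartition over", nrow(object@fractions), "genera\n")
  m <- 100 * colMeans(object@fractions)
  cat("  mean % of variance:\n")
  for (nm in names(m)) cat(sprintf("    %-12s %5.1f\n", nm, m[[nm]]))
  invisible(NULL)
})

#' @describeIn SeasonalPrediction-class compact display.
#' @param object a `SeasonalPrediction`.
#' @export
setMethod("show", "SeasonalPrediction", function(object) {
  tab <- table(factor(object@trendCall,
                      levels = c("increase", "decrease", "none")))
  cat("SeasonalPrediction for", length(object@pIncrease), "genera",
      sprintf("(%.0f%% rule):", 100 * object@threshold), "\n")
  cat(sprintf("  increase %d, decrease %d, none %d\n",
              tab[["increase"]], tab[["decrease"]], tab[["none"]]))
  invisible(NULL)
})

#' @describeIn OmegaSummary-class compact display.
#' @param object an `OmegaSummary`.
#' @export
setMethod("show", "OmegaSummary", function(object) {
  J <- nrow(object@omegaMean)
  off <- object@signCall[upper.tri(object@signCall)]
  cat(sprintf("OmegaSummary: %d genera, %d pairs (%.0f%% rule)\n",
              J, length(off), 100 * object@threshold))
  cat(sprintf("  sign calls: %d positive, %d negative\n",
              sum(off == 1), sum(off == -1)))
  invisible(NULL)
})
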