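## RRA filtering of genus count tables.
##
## Order of operations mirrors the conservative metabarcoding-style
## filtering chain: blank subtraction, cellwise RRA threshold, mean-RRA
## genus inclusion, optional dominant-taxon removal, then model-entry
## prevalence filtering. Thresholds are taken in percent (the field's
## notation) and held internally as proportions. Removal thresholds are
## strict ("< 0.001%", "less than 5%"), retention is inclusive (">= 0.01%").

.rraFromCounts <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2, tot, "/")
}

.asCounts <- function(x) {
  if (is(x, "HoneySkimExperiment")) countsMatrix(x) else as.matrix(x)
}

# rebuild the container around a modified / subsetted count matrix
.rewrap <- function(x, counts, blank = blankCounts(x)) {
  keep <- rownames(counts)
  tf <- traitFrame(x)
  HoneySkimExperiment(counts, sampleFrame(x),
                      traits = if (ncol(tf)) tf[keep, , drop = FALSE],
                      blank = if (!is.null(blank))
                        blank[intersect(names(blank), keep)],
                      truth = truthParams(x))
}

#' Subtract blank-control counts
#'
#' Reads observed in the no-template blank are taken as contamination and
#' subtracted, per genus, from every sample's count, clamped at zero.
#' Genera absent from the blank are unchanged.
#'
#' @param x a [HoneySkimExperiment-class] (or bare count matrix).
#' @param blank named nonnegative vector of blank counts; defaults to the
#'   blank stored in the object.
#' @return Same class as `x`, with corrected counts.
#' @export
subtractBlank <- function(x, blank = NULL) {
  counts <- .asCounts(x)
  if (is.null(blank) && is(x, "HoneySkimExperiment"))
    blank <- blankCounts(x)
  if (is.null(blank) || !length(blank)) return(x)
  if (any(blank < 0)) stop("blank counts must be nonnegative")
  unknown <- setdiff(names(blank), rownames(counts))
  blank <- blank[setdiff(names(blank), unknown)]
  counts[names(blank), ] <- pmax(counts[names(blank), , drop = FALSE] -
                                   blank, 0)
  if (is(x, "HoneySkimExperiment")) .rewrap(x, counts, blank = NULL)
  else counts
}

#' Relative read abundance per sample
#'
#' RRA of genus g in sample s is its read count divided by the sample's
#' total retained reads, so each sample column sums to one.
#'
#' @param x a [HoneySkimExperiment-class] or count matrix.
#' @return For a matrix input, the genus x sample RRA matrix; for a
#'   `HoneySkimExperiment`, the same object with an `"rra"` assay added.
#' @export
computeRRA <- function(x) {
  counts <- .asCounts(x)
  rra <- .rraFromCounts(counts)
  if (is(x, "HoneySkimExperiment")) {
    SummarizedExperiment::assay(x, "rra") <- rra
    x
  } else rra
}

#' Two-stage rare-taxon filter
#'
#' Stage one zeroes any genus x sample cell whose within-sample RRA is
#' strictly below `cellPct` percent (default 0.001%), removing likely
#' tag-jumping and misassignment artefacts. Stage two recomputes RRA and
#' drops genera whose unweighted mean RRA across samples is below
#' `meanPct` percent (default 0.01%); genera at exactly the threshold are
#' retained.
#'
#' @param x a [HoneySkimExperiment-class] or count matrix.
#' @param cellPct cellwise removal threshold, in percent.
#' @param meanPct mean-RRA inclusion threshold, in percent.
#' @param log environment or NULL; when an environment is given, the
#'   zeroed-cell count and removed genera are recorded in it.
#' @return Filtered object of the same class as `x`.
#' @export
filterRare <- function(x, cellPct = 0.001, meanPct = 0.01, log = NULL) {
  counts <- .asCounts(x)
  rra <- .rraFromCounts(counts)
  zero <- rra > 0 & rra < cellPct / 100
  counts[zero] <- 0
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) emptied by the cellwise filter: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  meanRra <- rowMeans(sweep(counts, 2, tot, "/"))
  keep <- meanRra >= meanPct / 100
  if (!is.null(log)) {
    log$cellsZeroed <- sum(zero)
    log$generaRemoved <- rownames(counts)[!keep]
    log$meanRra <- meanRra
  }
  counts <- counts[keep, , drop = FALSE]
  if (is(x, "HoneySkimExperiment")) .rewrap(x, counts) else counts
}

#' Remove dominant taxa and renormalize
#'
#' Because RRA is compositional, a strong surge of one taxon depresses the
#' apparent abundance of all others. This drops the named genera and
#' recomputes RRA over the remainder. The conventional dominant set for
#' honey skims is `c("Apilactobacillus", "Zygosaccharomyces", "AmFV")`.
#'
#' @param x a [HoneySkimExperiment-class], count matrix, or RRA matrix.
#' @param dominantIds character vector of genus ids to drop; ids absent
#'   from the table are an error.
#' @return Same class as `x` without the named genera (RRA renormalized
#'   when present).
#' @export
removeDominants <- function(x,
                            dominantIds = c("Apilactobacillus",
                                            "Zygosaccharomyces", "AmFV")) {
  if (!length(dominantIds)) return(x)
  m <- if (is(x, "HoneySkimExperiment")) countsMatrix(x) else as.matrix(x)
  unknown <- setdiff(dominantIds, rownames(m))
  if (length(unknown))
    stop("unknown genus id(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(rownames(m), dominantIds)
  m <- m[keep, , drop = FALSE]
  if (is(x, "HoneySkimExperiment")) return(.rewrap(x, m))
  # proportion input: renormalize over the remaining genera
  if (max(colSums(m)) <= 1 + 1e-9) return(.rraFromCounts(m))
  m
}

#' Prevalence filter for model entry
#'
#' Genera present in strictly less than `minPrevalence` of the samples
#' carry little information on occurrence drivers and are excluded from
#' both hurdle responses.
#'
#' @param Y binary genus x sample occurrence matrix, or a
#'   [HurdleResponse-class].
#' @param minPrevalence minimum occurrence fraction (default 0.05, i.e. 5%
#'   of samples).
#' @return Object of the same class restricted to retained genera.
#' @export
prevalenceFilter <- function(Y, minPrevalence = 0.05) {
  if (is(Y, "HurdleResponse")) {
    keep <- rowMeans(Y@Y) >= minPrevalence
    return(new("HurdleResponse", Y = Y@Y[keep, , drop = FALSE],
               Z = Y@Z[keep, , drop = FALSE],
               logTotalReads = Y@logTotalReads, samples = Y@samples))
  }
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  Y[rowMeans(Y) >= minPrevalence, , drop = FALSE]
}

#' Build the hurdle response pair
#'
#' `Y` marks presence (RRA > 0); `Z` is the natural log of RRA where
#' present and `NA` elsewhere; the per-sample log total reads (natural log)
#' is attached as the sequencing-effort covariate.
#'
#' @param x a [HoneySkimExperiment-class] (RRA computed if absent) or an
#'   RRA matrix.
#' @param samples per-sample design table; defaults to the object's.
#' @return A [HurdleResponse-class].
#' @export
buildHurdleResponse <- function(x, samples = NULL) {
  if (is(x, "HoneySkimExperiment")) {
    rra <- rraMatrix(x)
    if (is.null(samples)) samples <- sampleFrame(x)
  } else rra <- as.matrix(x)
  if (is.null(samples) || !identical(ncol(rra), nrow(samples)) ||
      !all(colnames(rra) == samples$sample))
    stop("sample table does not match the RRA columns")
  Y <- (rra > 0) * 1
  Z <- log(rra)
  Z[Y == 0] <- NA_real_
  new("HurdleResponse", Y = Y, Z = Z,
      logTotalReads = log(samples$totalReads), samples = samples)
}

#' Standard filtering chain
#'
#' Applies blank subtraction, the two-stage rare-taxon filter, optional
#' dominant-taxon removal, hurdle-response construction and the prevalence
#' filter in the stated order, recording per-stage genus counts.
#'
#' @param x a [HoneySkimExperiment-class].
#' @param cellPct,meanPct,minPrevalence thresholds in percent / proportion,
#'   see [filterRare()] and [prevalenceFilter()].
#' @param dominantIds genera to drop before building the abundance
#'   response, or `NULL` to keep all.
#' @return list with elements `response` (a [HurdleResponse-class]),
#'   `filtered` (the filtered experiment) and `log` (per-stage records).
#' @export
preprocessPipeline <- function(x, cellPct = 0.001, meanPct = 0.01,
                               minPrevalence = 0.05, dominantIds = NULL) {
  lg <- list(generaIn = nrow(x), samplesIn = ncol(x))
  x <- subtractBlank(x)
  lg$readsAfterBlank <- sum(countsMatrix(x))
  env <- new.env()
  x <- filterRare(x, cellPct, meanPct, log = env)
  lg$cellsZeroed <- env$cellsZeroed
  lg$generaRemovedRare <- env$generaRemoved
  if (!is.null(dominantIds)) {
    present <- intersect(dominantIds, rownames(x))
    if (length(present)) x <- removeDominants(x, present)
    lg$dominantsRemoved <- present
  }
  x <- computeRRA(x)
  resp <- buildHurdleResponse(x)
  respF <- prevalenceFilter(resp, minPrevalence)
  lg$generaRemovedPrevalence <- setdiff(rownames(resp@Y), rownames(respF@Y))
  lg$generaOut <- nrow(respF@Y)
  list(response = respF, filtered = x, log = lg)
}
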