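#' @rdname OTUTable-class
#' @param x an \code{OTUTable}.
#' @return \code{otuCounts} returns the integer count matrix (OTUs x
#'   samples).
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname OTUTable-class
#' @export
setGeneric("sampleScenario", function(x) standardGeneric("sampleScenario"))

#' @rdname OTUTable-class
#' @export
setGeneric("managementClass", function(x) standardGeneric("managementClass"))

#' @rdname OTUTable-class
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname PCAResult-class
#' @param x a result object.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname PCAResult-class
#' @export
setGeneric("variancePct", function(x) standardGeneric("variancePct"))

#' @rdname PCAResult-class
#' @export
setGeneric("loadings2", function(x) standardGeneric("loadings2"))

#' @rdname PCoAResult-class
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname MDSSelection-class
#' @export
setGeneric("mdsWeights", function(x) standardGeneric("mdsWeights"))

#' @rdname GroupComparisonResult-class
#' @export
setGeneric("groupLetters", function(x) standardGeneric("groupLetters"))

setMethod("otuCounts", "OTUTable", function(x)
  SummarizedExperiment::assay(x, "counts"))

setMethod("sampleScenario", "OTUTable", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$scenario),
           colnames(x)))

setMethod("managementClass", "OTUTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"management" %in% colnames(cd))
    stop("OTUTable has no 'management' column in colData")
  setNames(as.character(cd$management), colnames(x))
})

setMethod("taxonomyTable", "OTUTable", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(otu_id = rownames(x), rd, row.names = NULL,
             check.names = FALSE)
})

setMethod("eigenvalues", "PCAResult", function(x) x@eigenvalues)
setMethod("eigenvalues", "PCoAResult", function(x) x@eigenvalues)
setMethod("variancePct", "PCAResult", function(x) x@variancePct)
setMethod("loadings2", "PCAResult", function(x) x@loadings)
setMethod("coordinates", "PCoAResult", function(x) x@coordinates)
setMethod("mdsWeights", "MDSSelection", function(x) x@weights)
setMethod("groupLetters", "GroupComparisonResult", function(x) x@letters)

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec %s (%s): %d soil reps, %d microbiome reps\n",
              object@scenarioId, object@managementClass,
              object@nSoilReps, object@nMicrobiomeReps))
  cat(sprintf("  %d soil indicators, %d phyla in composition\n",
              length(object@soilMeans), length(object@phylumComposition)))
})

setMethod("show", "OTUTable", function(object) {
  cat(sprintf("OTUTable: %d OTUs x %d samples, %d scenarios\n",
              nrow(object), ncol(object),
              length(unique(sampleScenario(object)))))
  callNextMethod()
})

setMethod("show", "PCoAResult", function(object) {
  pos <- sum(object@eigenvalues > 0)
  cat(sprintf("PCoAResult: %d samples, %d positive eigenvalues, %d axes\n",
              nrow(object@coordinates), pos, ncol(object@coordinates)))
  if (length(object@proportionExplained))
    cat("  axis 1-2 explain:",
        paste0(sprintf("%.1f%%",
                       100 * utils::head(object@proportionExplained, 2)),
               collapse = ", "), "\n")
})

setMethod("show", "ANOSIMResult", function(object) {
  cat(sprintf("ANOSIM: R = %.5f, p = %.4g (%d permutations)\n",
              object@R, object@pValue, object@nPermutations))
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d variables\n", length(object@variableNames)))
  k <- min(4L, length(object@eigenvalues))
  tab <- rbind(Eigenvalue = round(object@eigenvalues[seq_len(k)], 2),
               `Variability (%)` = round(object@variancePct[seq_len(k)], 2),
               `Cumulative %` = round(object@cumulativePct[seq_len(k)], 2))
  colnames(tab) <- paste0("PC", seq_len(k))
  print(tab)
})

setMethod("show", "MDSSelection", function(object) {
  cat("MDSSelection:\n")
  for (pc in names(object@selectedIndicators))
    cat(sprintf("  %s: %s\n", pc,
                paste(object@selectedIndicators[[pc]], collapse = ", ")))
  cat("  weights:",
      paste(sprintf("%s=%.3f", names(object@weights), object@weights),
            collapse = ", "), "\n")
})

setMethod("show", "SQIResult", function(object) {
  cat(sprintf("SQIResult: %d observations, %d indicators\n",
              length(object@sqi), ncol(object@scores)))
  print(object@perScenario, digits = 3)
})

setMethod("show", "GroupComparisonResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              object@method, object@statistic, object@pValue, object@alpha))
  df <- data.frame(mean = object@groupMeans,
                   SE = object@groupSE,
                   n = object@groupN,
                   letter = object@letters[names(object@groupMeans)])
  print(df, digits = 4)
})
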