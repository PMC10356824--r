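#' @import methods
#' @importFrom stats anova aov cor cor.test kruskal.test lm pf pt qtukey
#'   quantile rgamma rmultinom rnorm sd setNames uniroot var
#' @importFrom utils combn read.table write.table
NULL

#' Scenario specification for the synthetic study generator
#'
#' A \code{ScenarioSpec} captures everything the simulator needs to emulate
#' one tillage-cum-crop-establishment scenario: per-indicator soil means and
#' standard errors (of the mean, n = 3 field replicates), the earthworm
#' density, the management class (farmers' practice \code{FP}, partial
#' conservation agriculture \code{pCA}, or full \code{CA}), and the expected
#' phylum-level community composition.
#'
#' @slot scenarioId single character label, e.g. \code{"scI"}.
#' @slot managementClass one of \code{"FP"}, \code{"pCA"}, \code{"CA"}.
#' @slot soilMeans named numeric vector of indicator means (units: pH
#'   unitless, EC dS/m, SOC g/kg, N/P/K kg/ha, Fe/Mn/Zn/Cu mg/kg).
#' @slot soilSEs named numeric vector of standard errors of the mean,
#'   same names as \code{soilMeans}, all \eqn{\ge 0}.
#' @slot earthwormMean mean earthworm count per cubic metre.
#' @slot earthwormSE standard error of the earthworm mean.
#' @slot phylumComposition named non-negative fractions summing to 1.
#' @slot nSoilReps number of soil replicates (default 3).
#' @slot nMicrobiomeReps number of microbiome replicates (default 5).
#'
#' @seealso [scenarioSpec()], [defaultStudySpecs()]
#' @export
setClass("ScenarioSpec",
  representation(
    scenarioId = "character",
    managementClass = "character",
    soilMeans = "numeric",
    soilSEs = "numeric",
    earthwormMean = "numeric",
    earthwormSE = "numeric",
    phylumComposition = "numeric",
    nSoilReps = "integer",
    nMicrobiomeReps = "integer"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (length(object@scenarioId) != 1L || !nzchar(object@scenarioId))
    msg <- c(msg, "scenarioId must be a single non-empty string")
  if (!object@managementClass %in% c("FP", "pCA", "CA"))
    msg <- c(msg, "managementClass must be one of FP, pCA, CA")
  if (!identical(sort(names(object@soilMeans)), sort(names(object@soilSEs))))
    msg <- c(msg, "soilMeans and soilSEs must share indicator names")
  if (any(object@soilSEs < 0) || object@earthwormSE < 0)
    msg <- c(msg, "standard errors must be >= 0")
  pc <- object@phylumComposition
  if (length(pc)) {
    if (any(pc < 0))
      msg <- c(msg, "phylumComposition must be non-negative")
    if (abs(sum(pc) - 1) > 1e-9)
      msg <- c(msg, "phylumComposition must sum to 1 (tolerance 1e-9)")
    if (is.null(names(pc)) || any(!nzchar(names(pc))))
      msg <- c(msg, "phylumComposition must be a named vector")
  }
  if (object@nSoilReps < 2L || object@nMicrobiomeReps < 2L)
    msg <- c(msg, "replicate counts must be >= 2")
  if (length(msg)) msg else TRUE
})

#' OTU count table with sample metadata and taxonomy
#'
#' \code{OTUTable} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}}: the
#' \code{"counts"} assay holds non-negative integer read counts with OTUs as
#' rows and samples as columns, \code{rowData} carries the GreenGenes-style
#' lineage (string plus parsed ranks), and \code{colData} maps samples to
#' scenarios and management classes.
#'
#' @seealso [makeOTUTable()], [simulateOTUTable()], [readOTUTable()]
#' @export
#' @import SummarizedExperiment
setClass("OTUTable", contains = "SummarizedExperiment")

setValidity("OTUTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("OTUTable requires a 'counts' assay")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (ncol(m) > 0 && any(colSums(m) == 0))
    msg <- c(msg, "no sample may be all-zero")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "OTU ids (rownames) and sample ids (colnames) are required")
  if (anyDuplicated(rownames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "OTU and sample ids must be unique")
  if (!"scenario" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'scenario' column")
  if (!"lineage" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'lineage' column")
  if (length(msg)) msg else TRUE
})

#' Principal coordinate analysis result
#'
#' @slot coordinates samples x axes matrix built on positive eigenvalues,
#'   column \code{k} scaled by \eqn{\sqrt{\lambda_k}}.
#' @slot eigenvalues all eigenvalues of the Gower-centred matrix, descending
#'   (negative ones reported, not used for coordinates).
#' @slot proportionExplained fraction of the positive-eigenvalue total
#'   carried by each retained axis.
#' @export
setClass("PCoAResult",
  representation(
    coordinates = "matrix",
    eigenvalues = "numeric",
    proportionExplained = "numeric"
  )
)

setValidity("PCoAResult", function(object) {
  if (ncol(object@coordinates) != length(object@proportionExplained))
    return("one proportion per coordinate axis required")
  if (length(object@proportionExplained) &&
      abs(sum(object@proportionExplained /
                sum(object@proportionExplained)) - 1) > 1e-9)
    return("proportions must be normalisable")
  TRUE
})

#' ANOSIM permutation-test result
#'
#' @slot R rank-based ANOSIM statistic in \eqn{[-1, 1]}.
#' @slot pValue permutation p-value, \eqn{(1+k)/(1+B)} estimator.
#' @slot nPermutations number of label permutations used.
#' @slot permutedR the permuted statistics (for diagnostics).
#' @slot seed seed used for the permutations.
#' @export
setClass("ANOSIMResult",
  representation(
    R = "numeric",
    pValue = "numeric",
    nPermutations = "integer",
    permutedR = "numeric",
    seed = "integer"
  )
)

setValidity("ANOSIMResult", function(object) {
  msg <- character()
  if (object@R < -1 - 1e-12 || object@R > 1 + 1e-12)
    msg <- c(msg, "R must lie in [-1, 1]")
  if (object@pValue < 1 / (object@nPermutations + 1) - 1e-12)
    msg <- c(msg, "p cannot undercut 1/(B+1)")
  if (length(msg)) msg else TRUE
})

#' Correlation-matrix PCA result
#'
#' Eigendecomposition of the correlation matrix of standardised indicators.
#' Loadings are eigenvectors scaled by the square root of their eigenvalue,
#' with the sign convention that the largest-|loading| variable of each PC
#' is positive.
#'
#' @slot eigenvalues descending eigenvalues; they sum to the number of
#'   variables.
#' @slot variancePct eigenvalue / p * 100.
#' @slot cumulativePct running sum of \code{variancePct}.
#' @slot loadings variables x PCs loading matrix.
#' @slot variableNames indicator names, in \code{loadings} row order.
#' @export
setClass("PCAResult",
  representation(
    eigenvalues = "numeric",
    variancePct = "numeric",
    cumulativePct = "numeric",
    loadings = "matrix",
    variableNames = "character"
  )
)

setValidity("PCAResult", function(object) {
  msg <- character()
  p <- length(object@variableNames)
  if (abs(sum(object@eigenvalues) - p) > 1e-6)
    msg <- c(msg, "correlation-PCA eigenvalues must sum to p")
  if (any(abs(object@loadings) > 1 + 1e-9))
    msg <- c(msg, "loadings must lie in [-1, 1]")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be descending")
  if (length(msg)) msg else TRUE
})

#' Minimum-data-set selection for the soil quality index
#'
#' @slot retainedPCs indices of PCs passing the eigenvalue/variance rules.
#' @slot selectedIndicators named list: per retained PC, surviving indicator
#'   names.
#' @slot weights named numeric, one weight per selected indicator, summing
#'   to 1.
#' @slot assignment named character mapping indicator -> PC label.
#' @slot trace data.frame audit trail of every selection rule decision.
#' @export
setClass("MDSSelection",
  representation(
    retainedPCs = "integer",
    selectedIndicators = "list",
    weights = "numeric",
    assignment = "character",
    trace = "data.frame"
  )
)

setValidity("MDSSelection", function(object) {
  msg <- character()
  if (length(object@weights)) {
    if (any(object@weights <= 0))
      msg <- c(msg, "weights must be positive")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1")
  }
  inds <- unlist(object@selectedIndicators, use.names = FALSE)
  if (anyDuplicated(inds))
    msg <- c(msg, "an indicator may be attributed to exactly one PC")
  if (length(msg)) msg else TRUE
})

#' Soil quality index result
#'
#' @slot scores per-observation indicator scores in (0, 1).
#' @slot sqi per-observation weighted index.
#' @slot perScenario data.frame of scenario mean, SE and n.
#' @slot observations the observation table the index was computed on.
#' @slot scoringParameters data.frame of a, b, x0 and direction per
#'   indicator.
#' @export
setClass("SQIResult",
  representation(
    scores = "matrix",
    sqi = "numeric",
    perScenario = "data.frame",
    observations = "data.frame",
    scoringParameters = "data.frame"
  )
)

#' Multi-group comparison result with compact letter display
#'
#' @slot method \code{"anova_dmrt"} or \code{"kruskal_wallis"}.
#' @slot statistic F (ANOVA) or tie-corrected H (Kruskal-Wallis).
#' @slot pValue overall test p-value.
#' @slot groupMeans named group means (ANOVA) or mean ranks (KW).
#' @slot groupSE named standard errors of group means.
#' @slot groupN named group sizes.
#' @slot letters named letter strings; groups sharing a letter are not
#'   significantly different.
#' @slot decisions logical matrix of pairwise "significantly different"
#'   verdicts (DMRT only; empty for KW).
#' @slot alpha significance level used.
#' @export
setClass("GroupComparisonResult",
  representation(
    method = "character",
    statistic = "numeric",
    pValue = "numeric",
    groupMeans = "numeric",
    groupSE = "numeric",
    groupN = "numeric",
    letters = "character",
    decisions = "matrix",
    alpha = "numeric"
  )
)

setValidity("GroupComparisonResult", function(object) {
  if (length(object@letters) && any(!nzchar(object@letters)))
    return("letter strings must be non-empty")
  TRUE
})
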