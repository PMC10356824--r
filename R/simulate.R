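# Deterministic fan-out of one global seed into per-scenario substream
# seeds: substream i is the i-th draw of sample.int() under the global seed,
# in the order the specs are supplied.
.substreamSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a replicate-level soil sample table
#'
#' Draws replicate values for every soil indicator as
#' Normal(mean, SE * sqrt(n)), reconstructing the replicate-level standard
#' deviation from the published standard error of the mean. Chemistry values
#' are truncated at a floor of 1e-6 of their mean (cosmetic: the study's
#' means are far from zero); earthworm counts are rounded half-up and
#' clipped at zero.
#'
#' @param specs a list of [ScenarioSpec-class] objects (see
#'   [defaultStudySpecs()]).
#' @param seed integer seed; one substream per scenario is derived from it
#'   in spec order, so output is reproducible and unaffected by other
#'   scenarios' draws.
#' @return a data.frame with columns \code{sample_id}, \code{scenario},
#'   \code{management}, \code{replicate}, one column per soil indicator and
#'   \code{earthworms}.
#' @examples
#' soil <- simulateSoilTable(defaultStudySpecs(), seed = 1)
#' head(soil)
#' @export
simulateSoilTable <- function(specs, seed) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  if (missing(seed)) stop("seed is required")
  lapply(specs, function(s) validObject(s))
  seeds <- .substreamSeeds(seed, length(specs))
  rows <- mapply(function(spec, sseed) {
    set.seed(sseed)
    n <- spec@nSoilReps
    vals <- vapply(names(spec@soilMeans), function(ind) {
      m <- spec@soilMeans[[ind]]
      x <- rnorm(n, mean = m, sd = spec@soilSEs[[ind]] * sqrt(n))
      pmax(x, 1e-6 * m)
    }, numeric(n))
    if (n == 1L) vals <- matrix(vals, nrow = 1L,
                                dimnames = list(NULL,
                                                names(spec@soilMeans)))
    ew <- rnorm(n, spec@earthwormMean, spec@earthwormSE * sqrt(n))
    ew <- pmax(0, floor(ew + 0.5))
    data.frame(sample_id = paste0(spec@scenarioId, "_r", seq_len(n)),
               scenario = spec@scenarioId,
               management = spec@managementClass,
               replicate = seq_len(n),
               vals,
               earthworms = as.integer(ew),
               check.names = FALSE)
  }, specs, seeds, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# GreenGenes-style lineage for simulated OTUs. Each phylum gets two
# synthetic classes and four orders so rank-level aggregation has structure
# to work with; "Other" keeps its label so the lumped mass stays traceable.
.makeLineages <- function(phyla, nPerPhylum) {
  unlist(mapply(function(ph, n) {
    k <- seq_len(n)
    cl <- paste0(ph, "_cl", (k - 1L) %% 2L + 1L)
    or <- paste0(ph, "_or", (k - 1L) %% 4L + 1L)
    paste0("k__Bacteria;p__", ph, ";c__", cl, ";o__", or, ";f__;g__")
  }, phyla, nPerPhylum, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Simulate an OTU count table with taxonomy
#'
#' Per sample, phylum proportions are drawn from a Dirichlet distribution
#' with concentration \code{theta * phylumComposition}; within each phylum,
#' OTU relative abundances follow a fixed geometric series (ratio
#' \code{geomRatio}), which yields realistic singleton/doubleton tails; read
#' counts are then drawn multinomially at the requested depth, so every
#' sample's row sum equals \code{depth} exactly.
#'
#' @param specs list of [ScenarioSpec-class] objects.
#' @param nOTUsPerPhylum single integer, or named integer vector per phylum
#'   (default 80 OTUs in each phylum's pool).
#' @param depth sequencing depth per sample (>= 1000).
#' @param theta Dirichlet concentration; between-replicate compositional
#'   variance shrinks as 1/theta.
#' @param geomRatio ratio of the within-phylum geometric abundance series.
#' @param seed integer seed (one substream per scenario, in spec order).
#' @return an [OTUTable-class] (counts assay OTUs x samples, lineage in
#'   \code{rowData}, scenario/management in \code{colData}).
#' @examples
#' specs <- defaultStudySpecs()[c("scI", "scIV")]
#' tab <- simulateOTUTable(specs, depth = 2000, seed = 1)
#' tab
#' @export
simulateOTUTable <- function(specs, nOTUsPerPhylum = 80L, depth = 60000L,
                             theta = 200, geomRatio = 0.7, seed) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  if (missing(seed)) stop("seed is required")
  if (depth < 1000) stop("depth must be >= 1000")
  if (theta <= 0) stop("theta must be > 0")
  if (geomRatio <= 0 || geomRatio >= 1)
    stop("geomRatio must lie in (0, 1)")
  lapply(specs, function(s) validObject(s))

  phyla <- unique(unlist(lapply(specs,
                                function(s) names(s@phylumComposition))))
  if (length(nOTUsPerPhylum) == 1L && is.null(names(nOTUsPerPhylum)))
    nOTUsPerPhylum <- setNames(rep(as.integer(nOTUsPerPhylum),
                                   length(phyla)), phyla)
  if (!all(phyla %in% names(nOTUsPerPhylum)))
    stop("nOTUsPerPhylum must cover every phylum in the specs")
  nOTUsPerPhylum <- as.integer(nOTUsPerPhylum[phyla])

  otuPhylum <- rep(phyla, nOTUsPerPhylum)
  otuIds <- sprintf("OTU%05d", seq_along(otuPhylum))
  lineages <- .makeLineages(phyla, nOTUsPerPhylum)
  # fixed within-phylum geometric abundance profile
  withinProfile <- unlist(lapply(nOTUsPerPhylum, function(n) {
    q <- geomRatio^(seq_len(n) - 1)
    q / sum(q)
  }), use.names = FALSE)

  seeds <- .substreamSeeds(seed, length(specs))
  blocks <- mapply(function(spec, sseed) {
    set.seed(sseed)
    comp <- spec@phylumComposition[phyla]
    comp[is.na(comp)] <- 0
    nrep <- spec@nMicrobiomeReps
    counts <- vapply(seq_len(nrep), function(r) {
      g <- rgamma(length(phyla), shape = theta * comp)
      if (sum(g) == 0) g[which.max(comp)] <- 1   # degenerate theta*comp
      dir <- g / sum(g)
      p <- dir[match(otuPhylum, phyla)] * withinProfile
      as.integer(rmultinom(1L, size = depth, prob = p))
    }, integer(length(otuPhylum)))
    colnames(counts) <- paste0(spec@scenarioId, "_m", seq_len(nrep))
    counts
  }, specs, seeds, SIMPLIFY = FALSE)
  counts <- do.call(cbind, blocks)
  rownames(counts) <- otuIds

  meta <- do.call(rbind, lapply(specs, function(spec)
    data.frame(scenario = spec@scenarioId,
               management = spec@managementClass,
               replicate = seq_len(spec@nMicrobiomeReps))))
  rownames(meta) <- colnames(counts)

  makeOTUTable(counts = t(counts),
               taxonomy = data.frame(otu_id = otuIds, lineage = lineages),
               metadata = meta)
}
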