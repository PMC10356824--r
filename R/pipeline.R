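#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' When \code{soilPath}/\code{otuPath} are \code{NULL} the study simulator
#' supplies the inputs (seed mandatory).
#'
#' @param seed integer seed for every source of randomness in the run.
#' @param outdir output directory (created if needed).
#' @param soilPath,otuPath,taxonomyPath,metadataPath optional input files;
#'   when absent, data are simulated from [defaultStudySpecs()].
#' @param depth,theta,nOTUsPerPhylum,geomRatio simulator settings.
#' @param rarefyDepth optional common depth for alpha diversity.
#' @param relative use relative abundances for Bray-Curtis.
#' @param grouping ANOSIM grouping: \code{"scenario"} or
#'   \code{"management"}.
#' @param nPermutations ANOSIM permutations.
#' @param alpha significance level used throughout.
#' @param eigMin,varMinPct,loadingWindow,loadingFloor,rMax MDS selection
#'   thresholds.
#' @param b scoring slope magnitude.
#' @param majorTaxaThreshold "others" lumping threshold.
#' @param networkPMax correlation-network edge threshold.
#' @return a list of class \code{casoil_config}.
#' @export
pipelineConfig <- function(seed, outdir,
                           soilPath = NULL, otuPath = NULL,
                           taxonomyPath = NULL, metadataPath = NULL,
                           depth = 60000L, theta = 200,
                           nOTUsPerPhylum = 80L, geomRatio = 0.7,
                           rarefyDepth = NULL, relative = FALSE,
                           grouping = c("scenario", "management"),
                           nPermutations = 999L, alpha = 0.05,
                           eigMin = 0.9, varMinPct = 5,
                           loadingWindow = 0.10, loadingFloor = 0.40,
                           rMax = 0.60, b = 2.5,
                           majorTaxaThreshold = 0.01,
                           networkPMax = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              soilPath = soilPath, otuPath = otuPath,
              taxonomyPath = taxonomyPath, metadataPath = metadataPath,
              depth = depth, theta = theta,
              nOTUsPerPhylum = nOTUsPerPhylum, geomRatio = geomRatio,
              rarefyDepth = rarefyDepth, relative = relative,
              grouping = match.arg(grouping),
              nPermutations = as.integer(nPermutations), alpha = alpha,
              eigMin = eigMin, varMinPct = varMinPct,
              loadingWindow = loadingWindow, loadingFloor = loadingFloor,
              rMax = rMax, b = b,
              majorTaxaThreshold = majorTaxaThreshold,
              networkPMax = networkPMax)
  class(cfg) <- "casoil_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate (unless inputs are supplied) then alpha diversity, beta
#' diversity with PCoA and ANOSIM, the soil quality index, the soil
#' group-statistics report, and the community-structure analytics. Every
#' table is written as TSV under \code{config$outdir} together with a JSON
#' manifest recording the seed, the effective thresholds and every output
#' file. Runs are byte-identical under an identical config.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory results and the manifest.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(seed = 1, outdir = tempfile(), depth = 2000)
#' res <- runPipeline(cfg)
#' res$anosim
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "casoil_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  files <- character(0)
  emit <- function(x, f, rowNamesAs = NULL) {
    .writeTSV(x, out(f), rowNamesAs = rowNamesAs)
    files <<- c(files, f)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  if (is.null(config$soilPath) || is.null(config$otuPath)) {
    specs <- defaultStudySpecs()
    soil <- stage("simulate", simulateSoilTable(specs, seed = config$seed))
    tab <- stage("simulate", simulateOTUTable(
      specs, nOTUsPerPhylum = config$nOTUsPerPhylum,
      depth = config$depth, theta = config$theta,
      geomRatio = config$geomRatio, seed = config$seed))
    emit(soil, "soil.tsv")
    stage("simulate", writeOTUTable(tab, out("otu_counts.tsv"),
                                    out("taxonomy.tsv"),
                                    out("sample_metadata.tsv")))
    files <- c(files, "otu_counts.tsv", "taxonomy.tsv",
               "sample_metadata.tsv")
  } else {
    soil <- stage("read", readSoilTable(config$soilPath))
    tab <- stage("read", readOTUTable(config$otuPath,
                                      taxonomyPath = config$taxonomyPath,
                                      metadataPath = config$metadataPath))
  }

  # --- alpha diversity ----------------------------------------------------
  alpha <- stage("alpha", alphaTable(tab,
                                     rarefyDepth = config$rarefyDepth,
                                     seed = config$seed))
  emit(alpha, "alpha_per_sample.tsv")
  emit(alphaSummary(alpha), "alpha_summary.tsv")

  # --- beta diversity -----------------------------------------------------
  D <- stage("beta", distanceMatrix(tab, relative = config$relative))
  emit(as.data.frame(D), "distance_matrix.tsv", rowNamesAs = "sample_id")
  pc <- stage("beta", pcoa(D, nAxes = 3L))
  emit(as.data.frame(coordinates(pc)), "pcoa_coordinates.tsv",
       rowNamesAs = "sample_id")
  emit(data.frame(axis = seq_along(eigenvalues(pc)),
                  eigenvalue = eigenvalues(pc)),
       "pcoa_eigenvalues.tsv")
  groups <- if (config$grouping == "scenario") sampleScenario(tab) else
    managementClass(tab)
  an <- stage("beta", anosimTest(D, groups,
                                 nPermutations = config$nPermutations,
                                 seed = config$seed))
  emit(data.frame(R = an@R, p = an@pValue,
                  permutations = an@nPermutations,
                  grouping = config$grouping, seed = an@seed),
       "anosim.tsv")

  # --- soil quality index -------------------------------------------------
  sqi <- stage("sqi", sqiPipeline(
    soil, alpha = config$alpha, b = config$b, eigMin = config$eigMin,
    varMinPct = config$varMinPct, loadingWindow = config$loadingWindow,
    loadingFloor = config$loadingFloor, rMax = config$rMax))
  emit(sqi$screen$audit, "sqi_screen.tsv")
  pcaTab <- data.frame(variable = sqi$pca@variableNames,
                       sqi$pca@loadings, check.names = FALSE)
  emit(rbind(
    data.frame(variable = "Eigenvalue",
               t(sqi$pca@eigenvalues), check.names = FALSE,
               row.names = NULL) |> setNames(colnames(pcaTab)),
    data.frame(variable = "Variability (%)", t(sqi$pca@variancePct),
               check.names = FALSE) |> setNames(colnames(pcaTab)),
    data.frame(variable = "Cumulative %", t(sqi$pca@cumulativePct),
               check.names = FALSE) |> setNames(colnames(pcaTab)),
    pcaTab), "sqi_pca.tsv")
  emit(sqi$selection@trace, "sqi_selection_trace.tsv")
  emit(data.frame(indicator = names(sqi$selection@weights),
                  pc = sqi$selection@assignment[
                    names(sqi$selection@weights)],
                  weight = unname(sqi$selection@weights)),
       "sqi_weights.tsv")
  emit(data.frame(soil[, c("sample_id", "scenario")],
                  sqi$sqi@scores, SQI = sqi$sqi@sqi,
                  check.names = FALSE),
       "sqi_per_observation.tsv")
  emit(sqi$sqi@perScenario, "sqi_summary.tsv")

  # --- soil group statistics ----------------------------------------------
  emit(stage("stats", compareAll(soil, groupColumn = "scenario",
                                 method = "dmrt",
                                 alpha = config$alpha)),
       "soil_dmrt.tsv")

  # --- community structure ------------------------------------------------
  comm <- list()
  for (rank in c("phylum", "order")) {
    rel <- stage("community", aggregateTaxa(tab, rank))
    major <- filterMajorTaxa(rel, config$majorTaxaThreshold)
    emit(as.data.frame(major), paste0("abundance_", rank, ".tsv"),
         rowNamesAs = "sample_id")
    comm[[rank]] <- major
  }
  phylumRel <- stage("community", aggregateTaxa(tab, "phylum"))
  ratio <- stage("community", copiotrophOligotrophRatio(phylumRel))
  emit(data.frame(sample_id = names(ratio),
                  scenario = sampleScenario(tab)[names(ratio)],
                  copiotroph_oligotroph = unname(ratio)),
       "copiotroph_ratio.tsv")
  venn <- stage("community", sharedOTUs(tab))
  emit(data.frame(subset = names(venn), otus = as.integer(venn)),
       "venn_counts.tsv")
  scen <- sampleScenario(tab)
  meanAb <- scenarioMeanAbundance(
    filterMajorTaxa(phylumRel, config$majorTaxaThreshold), scen)
  net <- stage("community",
               correlationNetwork(meanAb, abundanceMin = 0,
                                  pMax = config$networkPMax))
  emit(net$edges, "network_edges.tsv")
  emit(net$nodes, "network_nodes.tsv")

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "casoil",
    version = as.character(utils::packageVersion("casoil")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("outdir"))],
    outputs = sort(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  files <- c(files, "manifest.json")

  invisible(list(soil = soil, otu = tab, alpha = alpha, pcoa = pc,
                 anosim = an, sqi = sqi, community = comm,
                 ratio = ratio, venn = venn, network = net,
                 manifest = manifest))
}
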