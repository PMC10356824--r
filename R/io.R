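# TSV conventions: UTF-8, header row, dot decimal, tab separated.
.readTSV <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "",
             quote = "\"")
}

.writeTSV <- function(x, path, rowNamesAs = NULL) {
  if (!is.null(rowNamesAs)) {
    x <- data.frame(setNames(list(rownames(x)), rowNamesAs),
                    as.data.frame(x), check.names = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table (TSV or BIOM 1.0 JSON)
#'
#' TSV: samples as rows is the canonical orientation; a leading
#' \code{#OTU ID} header (QIIME convention) marks a transposed, OTUs-as-rows
#' file and is auto-detected. BIOM 1.0 JSON is read through the
#' \pkg{biomformat} package. Counts must be non-negative integers; ids
#' must be unique.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"biom1"}.
#' @param taxonomyPath 2-column TSV (otu_id, lineage); required for TSV
#'   input unless the BIOM file carries taxonomy observation metadata.
#' @param metadataPath TSV with columns \code{sample_id}, \code{scenario}
#'   and optionally \code{management}, \code{replicate}.
#' @return an [OTUTable-class].
#' @export
readOTUTable <- function(path, format = c("tsv", "biom1"),
                         taxonomyPath = NULL, metadataPath = NULL) {
  format <- match.arg(format)
  if (is.null(metadataPath))
    stop("metadataPath is required to map samples to scenarios")
  meta <- .readTSV(metadataPath)
  if (!all(c("sample_id", "scenario") %in% colnames(meta)))
    stop("metadata must have sample_id and scenario columns")
  rownames(meta) <- meta$sample_id

  if (format == "tsv") {
    firstLine <- readLines(path, n = 1L)
    transposed <- startsWith(firstLine, "#OTU ID")
    raw <- .readTSV(path)
    idCol <- colnames(raw)[1]
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- as.character(raw[[idCol]])
    if (transposed) m <- t(m)           # canonical: samples x OTUs
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
      stop("duplicated sample or OTU ids")
    if (!is.numeric(m) || any(is.na(m)) || any(m != round(m)) ||
        any(m < 0))
      stop("format error: counts must be non-negative integers")
    storage.mode(m) <- "integer"
    if (is.null(taxonomyPath))
      stop("taxonomyPath is required for TSV input")
    tax <- .readTSV(taxonomyPath)
    if (!all(c("otu_id", "lineage") %in% colnames(tax)))
      stop("taxonomy must have otu_id and lineage columns")
  } else {
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # samples x OTUs
    if (any(m != round(m)) || any(m < 0))
      stop("format error: counts must be non-negative integers")
    storage.mode(m) <- "integer"
    if (!is.null(taxonomyPath)) {
      tax <- .readTSV(taxonomyPath)
    } else {
      om <- biomformat::observation_metadata(b)
      if (is.null(om)) stop("BIOM file has no taxonomy; supply ",
                            "taxonomyPath")
      lin <- apply(as.matrix(om), 1, paste, collapse = ";")
      tax <- data.frame(otu_id = colnames(m), lineage = unname(lin))
    }
  }
  makeOTUTable(m, tax, meta)
}

#' Write an OTU table, its taxonomy and metadata as TSV
#'
#' @param otuTable an [OTUTable-class].
#' @param countsPath counts TSV (samples as rows).
#' @param taxonomyPath optional 2-column taxonomy TSV.
#' @param metadataPath optional sample metadata TSV.
#' @return invisibly, the counts path.
#' @export
writeOTUTable <- function(otuTable, countsPath, taxonomyPath = NULL,
                          metadataPath = NULL) {
  m <- t(otuCounts(otuTable))
  .writeTSV(m, countsPath, rowNamesAs = "sample_id")
  if (!is.null(taxonomyPath)) {
    tax <- taxonomyTable(otuTable)
    .writeTSV(tax[, c("otu_id", "lineage")], taxonomyPath)
  }
  if (!is.null(metadataPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(otuTable))
    .writeTSV(data.frame(sample_id = colnames(otuTable), cd,
                         check.names = FALSE), metadataPath)
  }
  invisible(countsPath)
}

.soilRequired <- c("sample_id", "scenario", "replicate")

#' Read a replicate-level soil table (TSV)
#'
#' Validates the schema: \code{sample_id}, \code{scenario},
#' \code{replicate}, at least one indicator column, all chemistry values
#' strictly positive, earthworm counts non-negative integers.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSoilTable <- function(path) {
  soil <- .readTSV(path)
  missing <- setdiff(.soilRequired, colnames(soil))
  if (length(missing))
    stop("soil table schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  vals <- .soilValueColumns(soil)
  if (!length(vals)) stop("soil table has no indicator columns")
  for (v in setdiff(vals, "earthworms")) {
    if (!is.numeric(soil[[v]]) || any(soil[[v]] <= 0))
      stop("soil indicator ", v, " must be strictly positive")
  }
  if ("earthworms" %in% vals) {
    ew <- soil$earthworms
    if (any(ew < 0) || any(ew != round(ew)))
      stop("earthworms must be non-negative integers")
  }
  soil
}

#' Write a soil table as TSV
#' @param soil data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSoilTable <- function(soil, path) .writeTSV(soil, path)
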