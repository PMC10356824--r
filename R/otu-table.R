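.lineageRanks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Parse GreenGenes-style lineage strings
#'
#' Splits strings like \code{"k__Bacteria;p__Proteobacteria;c__;o__;f__;g__"}
#' into one column per rank (kingdom to genus). Missing or empty ranks are
#' stored as \code{""}; consumers render them as \code{"unclassified"}.
#'
#' @param lineage character vector of lineage strings.
#' @return data.frame with columns kingdom, phylum, class, order, family,
#'   genus.
#' @examples
#' parseLineage("k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__;g__")
#' @export
parseLineage <- function(lineage) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  out <- matrix("", nrow = length(lineage), ncol = length(.lineageRanks),
                dimnames = list(NULL, .lineageRanks))
  parts <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    for (tok in trimws(parts[[i]])) {
      j <- match(substr(tok, 1, 3), prefixes)
      if (!is.na(j)) out[i, j] <- trimws(substring(tok, 4))
    }
  }
  as.data.frame(out)
}

#' Construct an OTUTable
#'
#' @param counts integer count matrix, samples as rows and OTUs as columns
#'   (the canonical interchange orientation); row and column names required.
#' @param taxonomy data.frame with columns \code{otu_id} and \code{lineage}
#'   covering every OTU in \code{counts}.
#' @param metadata data.frame with rownames matching the sample ids and at
#'   least a \code{scenario} column (a \code{management} column enables
#'   class-level analyses).
#' @return an [OTUTable-class].
#' @examples
#' cm <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'              dimnames = list(c("s1", "s2"), c("otuA", "otuB")))
#' tax <- data.frame(otu_id = c("otuA", "otuB"),
#'                   lineage = c("k__Bacteria;p__Firmicutes",
#'                               "k__Bacteria;p__Proteobacteria"))
#' meta <- data.frame(scenario = c("scI", "scII"),
#'                    row.names = c("s1", "s2"))
#' makeOTUTable(cm, tax, meta)
#' @export
makeOTUTable <- function(counts, taxonomy, metadata) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs sample ids as rownames and OTU ids as colnames")
  missing <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(missing))
    stop("missing lineage for OTU(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!all(rownames(counts) %in% rownames(metadata)))
    stop("metadata must cover every sample id")
  tax <- taxonomy[match(colnames(counts), taxonomy$otu_id), , drop = FALSE]
  rowDat <- S4Vectors::DataFrame(lineage = tax$lineage,
                                 parseLineage(tax$lineage),
                                 row.names = colnames(counts))
  colDat <- S4Vectors::DataFrame(
    metadata[rownames(counts), , drop = FALSE])
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    rowData = rowDat, colData = colDat)
  new("OTUTable", se)
}
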