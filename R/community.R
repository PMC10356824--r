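#' Aggregate OTU counts to a taxonomic rank
#'
#' Sums counts by the chosen rank's taxon (an empty rank becomes
#' \code{"unclassified"}) and converts to per-sample relative abundances.
#'
#' @param otuTable an [OTUTable-class].
#' @param rank \code{"phylum"}, \code{"class"} or \code{"order"}.
#' @return samples x taxa matrix of fractions (rows sum to 1), with
#'   attributes \code{rank} and \code{counts} (the unnormalised samples x
#'   taxa count matrix).
#' @export
aggregateTaxa <- function(otuTable, rank = c("phylum", "class", "order")) {
  rank <- match.arg(rank)
  rd <- SummarizedExperiment::rowData(otuTable)
  taxa <- as.character(rd[[rank]])
  taxa[is.na(taxa) | !nzchar(taxa)] <- "unclassified"
  m <- otuCounts(otuTable)              # OTUs x samples
  agg <- rowsum(m, group = taxa)        # taxa x samples
  counts <- t(agg)                      # samples x taxa
  rel <- counts / rowSums(counts)
  attr(rel, "rank") <- rank
  attr(rel, "counts") <- counts
  rel
}

#' Lump minor taxa into "others"
#'
#' Taxa whose mean relative abundance across all samples falls below the
#' threshold are summed into an \code{"others"} column; rows still sum
#' to 1.
#'
#' @param m samples x taxa relative-abundance matrix.
#' @param threshold mean-abundance cutoff (default 0.01, i.e. 1 percent).
#' @return filtered matrix, major taxa first, \code{"others"} last (only
#'   present when something was lumped).
#' @export
filterMajorTaxa <- function(m, threshold = 0.01) {
  keep <- colMeans(m) >= threshold
  if (all(keep)) return(m)
  out <- m[, keep, drop = FALSE]
  others <- rowSums(m[, !keep, drop = FALSE])
  if ("others" %in% colnames(out)) {
    out[, "others"] <- out[, "others"] + others
  } else {
    out <- cbind(out, others = others)
  }
  attr(out, "rank") <- attr(m, "rank")
  out
}

#' Copiotroph / oligotroph abundance ratio
#'
#' Proteobacteria (copiotrophic) over Acidobacteria + Chloroflexi
#' (oligotrophic), a proxy for soil nutrient availability. Samples with a
#' zero denominator get \code{NA} (flagged undefined).
#'
#' @param m samples x taxa matrix at phylum rank; the three phyla must be
#'   present as columns (zeros allowed).
#' @return named numeric vector, one ratio per sample.
#' @export
copiotrophOligotrophRatio <- function(m) {
  need <- c("Proteobacteria", "Acidobacteria", "Chloroflexi")
  missing <- setdiff(need, colnames(m))
  if (length(missing))
    stop("phylum column(s) missing: ", paste(missing, collapse = ", "))
  den <- m[, "Acidobacteria"] + m[, "Chloroflexi"]
  ratio <- ifelse(den == 0, NA_real_, m[, "Proteobacteria"] / den)
  setNames(ratio, rownames(m))
}

#' Shared and unique OTUs across management classes
#'
#' An OTU is "present" in a management class when it is detected at
#' \code{minCount} reads or more in strictly more than
#' \code{minFractionOfSamples} of that class's samples (defaults: at least
#' one read in at least one sample). Returns the exact partition of OTUs
#' over the non-empty subsets of classes.
#'
#' @param otuTable an [OTUTable-class] whose \code{colData} has a
#'   \code{management} column.
#' @param minCount detection threshold per sample.
#' @param minFractionOfSamples class-level prevalence threshold.
#' @return named integer vector: one entry per non-empty class subset
#'   (names like \code{"FP"}, \code{"FP&CA"}, \code{"FP&pCA&CA"}), plus
#'   attribute \code{membership} (the per-class presence matrix).
#' @export
sharedOTUs <- function(otuTable, minCount = 1L,
                       minFractionOfSamples = 0) {
  cls <- managementClass(otuTable)
  if (any(is.na(cls) | !nzchar(cls)))
    stop("every sample must be mapped to a management class")
  m <- otuCounts(otuTable)              # OTUs x samples
  classes <- intersect(c("FP", "pCA", "CA"), unique(cls))
  classes <- c(classes, setdiff(unique(cls), classes))
  present <- vapply(classes, function(cl) {
    sub <- m[, cls == cl, drop = FALSE]
    rowMeans(sub >= minCount) > minFractionOfSamples
  }, logical(nrow(m)))
  anywhere <- rowSums(present) > 0
  subsets <- unlist(lapply(seq_along(classes), function(k)
    combn(classes, k, paste, collapse = "&", simplify = FALSE)))
  counts <- vapply(subsets, function(s) {
    members <- strsplit(s, "&", fixed = TRUE)[[1]]
    inSet <- rowSums(present[, members, drop = FALSE]) == length(members) &
      rowSums(present[, setdiff(classes, members), drop = FALSE]) == 0
    sum(inSet)
  }, integer(1))
  out <- setNames(counts, subsets)
  attr(out, "membership") <- present
  attr(out, "total") <- sum(anywhere)
  out
}

#' Pearson correlation network among major taxa
#'
#' Pairwise Pearson correlations among taxa whose mean abundance passes
#' \code{abundanceMin}; edges are kept when the two-sided p-value is at
#' most \code{pMax}. Constant taxa are excluded with a warning. No
#' multiple-testing correction is applied by default (an optional
#' Benjamini-Hochberg adjustment is available).
#'
#' @param m observations x taxa abundance matrix (per-scenario means give
#'   the scale of a 7-point correlation; per-sample abundances are also
#'   accepted).
#' @param abundanceMin mean-abundance threshold for node inclusion.
#' @param pMax edge significance threshold.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return list with \code{nodes} (taxon, mean abundance) and \code{edges}
#'   (taxon1, taxon2, r, p, sign).
#' @export
correlationNetwork <- function(m, abundanceMin = 0.01, pMax = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (nrow(m) < 4) stop("need at least 4 observations")
  m <- m[, colMeans(m) >= abundanceMin, drop = FALSE]
  constant <- apply(m, 2, sd) == 0
  if (any(constant)) {
    warning("constant taxa excluded: ",
            paste(colnames(m)[constant], collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  taxa <- colnames(m)
  nodes <- data.frame(taxon = taxa, mean_abundance = colMeans(m))
  rownames(nodes) <- NULL
  if (length(taxa) < 2)
    return(list(nodes = nodes,
                edges = data.frame(taxon1 = character(0),
                                   taxon2 = character(0), r = numeric(0),
                                   p = numeric(0), sign = character(0))))
  pairs <- combn(taxa, 2)
  edges <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pc <- pearsonCorrelation(m[, pairs[1, k]], m[, pairs[2, k]])
    data.frame(taxon1 = pairs[1, k], taxon2 = pairs[2, k],
               r = pc$r, p = pc$p)
  }))
  if (adjust == "BH") edges$p <- stats::p.adjust(edges$p, method = "BH")
  edges <- edges[edges$p <= pMax, , drop = FALSE]
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Per-scenario mean taxa abundances
#'
#' @param m samples x taxa abundance matrix.
#' @param scenario scenario label per sample (rows of \code{m}).
#' @return scenarios x taxa matrix of mean abundances.
#' @export
scenarioMeanAbundance <- function(m, scenario) {
  out <- rowsum(m, group = scenario) /
    as.vector(table(scenario)[sort(unique(scenario))])
  out[sort(unique(scenario)), , drop = FALSE]
}
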