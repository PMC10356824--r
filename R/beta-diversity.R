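#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{\sum_i |x_i - y_i| / \sum_i (x_i + y_i)}.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return dissimilarity in \eqn{[0, 1]}.
#' @examples
#' brayCurtis(c(1, 1, 0), c(0, 1, 1))   # 0.5
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero samples")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param otuTable an [OTUTable-class] (or a samples x OTUs numeric
#'   matrix).
#' @param relative transform counts to per-sample relative abundances
#'   first (default \code{FALSE}: raw counts).
#' @return symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
distanceMatrix <- function(otuTable, relative = FALSE) {
  m <- if (is(otuTable, "OTUTable")) t(otuCounts(otuTable)) else
    as.matrix(otuTable)
  if (relative) m <- m / rowSums(m)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- brayCurtis(m[i, ], m[j, ])
    }
  }
  D
}

#' Principal coordinate analysis
#'
#' Gower double-centring \eqn{B = -\frac12 J (D \circ D) J} with
#' \eqn{J = I - \mathbf{1}\mathbf{1}^T/n}, symmetric eigendecomposition,
#' axes sorted by descending eigenvalue. Coordinates are built only on
#' positive eigenvalues (column k scaled by \eqn{\sqrt{\lambda_k}});
#' negative eigenvalues are reported but excluded from coordinates and
#' explained proportions (no Lingoes/Cailliez correction). Axis signs are
#' fixed so that each axis's largest-magnitude coordinate is positive.
#'
#' @param D symmetric dissimilarity matrix (e.g. from
#'   [distanceMatrix()]).
#' @param nAxes maximum number of axes to return.
#' @return a [PCoAResult-class].
#' @export
pcoa <- function(D, nAxes = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  eig <- e$values
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  if (length(pos) < 2)
    warning("degenerate configuration: fewer than 2 positive eigenvalues")
  keep <- pos[seq_len(min(length(pos), nAxes))]
  if (length(keep) == 0L) {
    coords <- matrix(numeric(0), nrow = n, ncol = 0,
                     dimnames = list(rownames(D), NULL))
    prop <- numeric(0)
  } else {
    coords <- sweep(e$vectors[, keep, drop = FALSE], 2,
                    sqrt(eig[keep]), `*`)
    # deterministic sign: largest-|entry| coordinate positive per axis
    for (k in seq_len(ncol(coords))) {
      idx <- which.max(abs(coords[, k]))
      if (coords[idx, k] < 0) coords[, k] <- -coords[, k]
    }
    dimnames(coords) <- list(rownames(D),
                             paste0("Axis", seq_along(keep)))
    prop <- eig[keep] / sum(eig[pos])
  }
  new("PCoAResult", coordinates = coords, eigenvalues = eig,
      proportionExplained = prop)
}

.anosimR <- function(rankD, within, M) {
  (mean(rankD[!within]) - mean(rankD[within])) / (M / 2)
}

#' ANOSIM permutation test
#'
#' Rank-based analysis of group similarities. All
#' \eqn{M = n(n-1)/2} off-diagonal dissimilarities are ranked (average
#' ranks for ties) and
#' \eqn{R = (\bar r_{between} - \bar r_{within}) / (M/2)}. The p-value is
#' the seeded label-permutation estimate \eqn{(1 + k)/(1 + B)} with k the
#' number of permuted statistics \eqn{\ge} the observed one.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param nPermutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return an [ANOSIMResult-class].
#' @export
anosimTest <- function(D, groups, nPermutations = 999L, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) stop("ANOSIM needs at least 2 groups")
  if (any(tab < 2)) stop("invalid grouping: every group needs >= 2 samples")
  idx <- which(lower.tri(D))
  rankD <- rank(D[idx])
  M <- length(idx)
  pairRows <- row(D)[idx]
  pairCols <- col(D)[idx]
  within <- groups[pairRows] == groups[pairCols]
  Robs <- .anosimR(rankD, within, M)
  set.seed(as.integer(seed))
  permR <- vapply(seq_len(nPermutations), function(b) {
    g <- sample(groups)
    .anosimR(rankD, g[pairRows] == g[pairCols], M)
  }, numeric(1))
  p <- (1 + sum(permR >= Robs)) / (nPermutations + 1)
  new("ANOSIMResult", R = Robs, pValue = p,
      nPermutations = as.integer(nPermutations), permutedR = permR,
      seed = as.integer(seed))
}
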