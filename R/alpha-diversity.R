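.checkCounts <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts
}

#' Shannon diversity index (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over the positive counts, with
#' \eqn{p_i = c_i / N}. Values are in nats.
#'
#' @param counts integer count vector.
#' @return Shannon index in nats.
#' @examples
#' shannonIndex(c(5, 5, 5, 5))   # log(4)
#' @export
shannonIndex <- function(counts) {
  .checkCounts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty sample: all counts are zero")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' \eqn{1 - \sum p_i^2}: the probability that two randomly drawn reads
#' belong to different OTUs. \code{finiteSample = TRUE} gives the unbiased
#' finite-sample form \eqn{1 - \sum c_i (c_i - 1) / (N (N - 1))}.
#'
#' @param counts integer count vector.
#' @param finiteSample use the finite-sample correction.
#' @return value in \eqn{[0, 1)}.
#' @export
simpsonIndex <- function(counts, finiteSample = FALSE) {
  .checkCounts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty sample: all counts are zero")
  N <- sum(counts)
  if (finiteSample) {
    if (N < 2) stop("finite-sample form needs at least 2 reads")
    1 - sum(counts * (counts - 1)) / (N * (N - 1))
  } else {
    1 - sum((counts / N)^2)
  }
}

#' Chao1 richness estimator
#'
#' Bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} by default (well defined
#' even with no doubletons); \code{biasCorrected = FALSE} gives the classic
#' \eqn{S_{obs} + F_1^2 / (2 F_2)}.
#'
#' @param counts integer count vector.
#' @param biasCorrected logical.
#' @return estimated richness, always \eqn{\ge S_{obs}}.
#' @export
chao1 <- function(counts, biasCorrected = TRUE) {
  .checkCounts(counts)
  counts <- counts[counts > 0]
  S <- length(counts)
  F1 <- sum(counts == 1)
  F2 <- sum(counts == 2)
  if (biasCorrected) S + F1 * (F1 - 1) / (2 * (F2 + 1))
  else if (F1 == 0) S
  else S + F1^2 / (2 * F2)
}

#' ACE richness estimator
#'
#' Abundance-based coverage estimator with rare/abundant split at
#' \code{rareCutoff} (default 10):
#' \eqn{S_{abund} + S_{rare}/C + (F_1/C)\,\gamma^2} with sample coverage
#' \eqn{C = 1 - F_1 / N_{rare}} and the squared coefficient of variation
#' \eqn{\gamma^2} clamped at zero. When every rare OTU is a singleton
#' (\eqn{C = 0}) the estimator is undefined and the function falls back to
#' [chao1()] with a warning.
#'
#' @param counts integer count vector.
#' @param rareCutoff maximum count for the "rare" group.
#' @return estimated richness.
#' @export
ace <- function(counts, rareCutoff = 10L) {
  .checkCounts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty sample: all counts are zero")
  rare <- counts[counts <= rareCutoff]
  Sabund <- sum(counts > rareCutoff)
  Srare <- length(rare)
  if (Srare == 0) return(Sabund)
  Nrare <- sum(rare)
  F1 <- sum(rare == 1)
  Cace <- 1 - F1 / Nrare
  if (Cace == 0) {
    warning("ACE undefined (all rare OTUs are singletons); ",
            "falling back to Chao1")
    return(chao1(counts))
  }
  Fi <- tabulate(rare, nbins = rareCutoff)
  i <- seq_len(rareCutoff)
  gamma2 <- max(Srare / Cace * sum(i * (i - 1) * Fi) /
                  (Nrare * (Nrare - 1)) - 1, 0)
  Sabund + Srare / Cace + (F1 / Cace) * gamma2
}

#' Fisher's alpha
#'
#' The unique \eqn{\alpha > 0} solving
#' \eqn{S = \alpha \ln(1 + N/\alpha)} for observed richness S and total
#' reads N, found by bracketed root-finding to \eqn{|f| < 10^{-10}}.
#'
#' @param counts integer count vector; requires \eqn{N > S} strictly.
#' @return Fisher's alpha.
#' @export
fisherAlpha <- function(counts) {
  .checkCounts(counts)
  counts <- counts[counts > 0]
  S <- length(counts)
  N <- sum(counts)
  if (S == 0) stop("empty sample: all counts are zero")
  if (S >= N)
    stop("Fisher's alpha diverges when every read is a singleton (S = N)")
  f <- function(a) a * log(1 + N / a) - S
  lo <- 1e-12
  hi <- max(S, 1)
  while (f(hi) < 0) hi <- hi * 2
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # polish by Newton steps until the defining identity is tight
  for (it in 1:50) {
    fr <- f(root)
    if (abs(fr) < 1e-10) break
    dfr <- log(1 + N / root) - N / (root + N)
    root <- root - fr / dfr
  }
  root
}

#' Observed OTU richness
#'
#' @param counts integer count vector.
#' @return number of strictly positive entries.
#' @export
observedOTUs <- function(counts) {
  .checkCounts(counts)
  sum(counts > 0)
}

#' Exact rarefaction curve
#'
#' Expected richness in a random subsample of n reads without replacement:
#' \eqn{E[S_n] = \sum_i (1 - \binom{N - c_i}{n} / \binom{N}{n})}, computed
#' in log space for numerical stability.
#'
#' @param counts integer count vector.
#' @param depths increasing integer subsample sizes, each \eqn{\le N}.
#' @return data.frame with columns \code{depth} and
#'   \code{expected_richness}.
#' @export
rarefactionCurve <- function(counts, depths) {
  .checkCounts(counts)
  counts <- counts[counts > 0]
  N <- sum(counts)
  depths <- as.integer(depths)
  if (any(depths < 1) || any(depths > N))
    stop("invalid depth: each depth must lie in [1, ", N, "]")
  er <- vapply(depths, function(n) {
    keepProb <- 1 - exp(lchoose(N - counts, n) - lchoose(N, n))
    sum(keepProb)
  }, numeric(1))
  data.frame(depth = depths, expected_richness = er)
}

#' Per-sample alpha-diversity table
#'
#' Applies all estimators to every sample of an OTU table.
#'
#' @param otuTable an [OTUTable-class].
#' @param rarefyDepth optional common depth: samples are rarefied (expected
#'   values are not used; counts are subsampled without replacement,
#'   seeded) before index computation. Default \code{NULL}: raw counts.
#' @param seed seed used only when \code{rarefyDepth} is given.
#' @return data.frame with one row per sample: observed_otus, shannon,
#'   simpson, chao1, ace, fisher_alpha, plus scenario metadata.
#' @export
alphaTable <- function(otuTable, rarefyDepth = NULL, seed = 1L) {
  m <- otuCounts(otuTable)   # OTUs x samples
  scen <- sampleScenario(otuTable)
  if (!is.null(rarefyDepth)) {
    set.seed(seed)
    m <- apply(m, 2, function(cnt) {
      if (sum(cnt) < rarefyDepth)
        stop("rarefyDepth exceeds the depth of a sample")
      reads <- rep(seq_along(cnt), cnt)
      tabulate(sample(reads, rarefyDepth), nbins = length(cnt))
    })
  }
  rows <- lapply(colnames(m), function(sid) {
    cnt <- m[, sid]
    tryCatch(
      data.frame(sample_id = sid, scenario = scen[[sid]],
                 observed_otus = observedOTUs(cnt),
                 shannon = shannonIndex(cnt),
                 simpson = simpsonIndex(cnt),
                 chao1 = chao1(cnt),
                 ace = ace(cnt),
                 fisher_alpha = fisherAlpha(cnt)),
      error = function(e) stop("sample ", sid, ": ", conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-scenario alpha-diversity summary (mean and SE)
#'
#' @param alpha data.frame from [alphaTable()].
#' @return data.frame of per-scenario mean and standard error for each
#'   index.
#' @export
alphaSummary <- function(alpha) {
  idx <- setdiff(colnames(alpha), c("sample_id", "scenario"))
  out <- do.call(rbind, lapply(split(alpha, alpha$scenario), function(d) {
    row <- data.frame(scenario = d$scenario[1], n = nrow(d))
    for (v in idx) {
      row[[paste0(v, "_mean")]] <- mean(d[[v]])
      row[[paste0(v, "_se")]] <- sd(d[[v]]) / sqrt(nrow(d))
    }
    row
  }))
  rownames(out) <- NULL
  out[order(out$scenario), , drop = FALSE]
}
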