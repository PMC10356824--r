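.soilValueColumns <- function(soil) {
  setdiff(colnames(soil),
          c("sample_id", "scenario", "management", "replicate"))
}

#' Screen soil indicators by one-way ANOVA across scenarios
#'
#' Indicators whose one-way ANOVA across scenarios reaches \eqn{p \le
#' \alpha} are retained for the minimum data set. An indicator with zero
#' within-group variance everywhere cannot be tested; it is retained with a
#' warning and flagged in the audit table.
#'
#' @param soil replicate-level soil table (see [simulateSoilTable()]).
#' @param alpha significance level (default 0.05).
#' @param indicators columns to screen; defaults to every value column.
#' @return list with \code{retained} (character vector) and \code{audit}
#'   (data.frame of F, p and the verdict per indicator).
#' @export
screenIndicators <- function(soil, alpha = 0.05, indicators = NULL) {
  if (is.null(indicators)) indicators <- .soilValueColumns(soil)
  if (length(unique(soil$scenario)) < 2)
    stop("screening needs at least 2 scenarios")
  audit <- do.call(rbind, lapply(indicators, function(ind) {
    res <- tryCatch(anovaOneway(soil[[ind]], soil$scenario),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("indicator ", ind, " could not be tested (",
              conditionMessage(res), "); retained")
      data.frame(indicator = ind, F = NA_real_, p = NA_real_,
                 retained = TRUE, note = conditionMessage(res))
    } else {
      data.frame(indicator = ind, F = res$F, p = res$p,
                 retained = res$p <= alpha, note = "")
    }
  }))
  rownames(audit) <- NULL
  list(retained = audit$indicator[audit$retained], audit = audit)
}

#' Correlation-matrix principal component analysis
#'
#' Columns are z-scored (sample standard deviation, denominator n - 1) and
#' the correlation matrix eigendecomposed. Loadings are eigenvectors scaled
#' by \eqn{\sqrt{\lambda}}; each PC's sign is flipped so its
#' largest-|loading| variable is positive. Variance percentages are
#' \eqn{\lambda / p \times 100}.
#'
#' @param X numeric matrix or data.frame, observations x indicators.
#' @return a [PCAResult-class].
#' @export
pcaCorrelation <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("PCA needs at least 3 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- cor(X)
  e <- eigen(R, symmetric = TRUE)
  eig <- pmax(e$values, 0)
  p <- ncol(X)
  loadings <- sweep(e$vectors, 2, sqrt(eig), `*`)
  for (k in seq_len(p)) {
    idx <- which.max(abs(loadings[, k]))
    if (loadings[idx, k] < 0) loadings[, k] <- -loadings[, k]
  }
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(p)))
  vp <- e$values / p * 100
  new("PCAResult", eigenvalues = e$values, variancePct = vp,
      cumulativePct = cumsum(vp), loadings = loadings,
      variableNames = colnames(X))
}

#' PCA variance percentages from eigenvalues
#'
#' Desk-check helper: for a correlation-matrix PCA on p variables, each
#' PC's share of the variance is eigenvalue / p * 100.
#'
#' @param eigenvalues numeric eigenvalues.
#' @param p number of variables.
#' @return percentages, same length as \code{eigenvalues}.
#' @examples
#' pcaVariancePct(c(7.75, 5.26, 3.68), p = 21)
#' @export
pcaVariancePct <- function(eigenvalues, p) {
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  eigenvalues / p * 100
}

#' Minimum-data-set selection from a PCA
#'
#' Applies the four-rule MDS procedure: (1) retain PCs with eigenvalue
#' \eqn{\ge} \code{eigMin} that explain more than \code{varMinPct} percent
#' of the variance; (2) within each retained PC, candidate indicators have
#' |loading| within \code{loadingWindow} (fraction) of the PC's highest
#' |loading|, or |loading| \eqn{\ge} \code{loadingFloor}; (3) if a PC
#' yields several candidates, pairwise Pearson correlations on the data
#' decide: all are kept when every |r| < \code{rMax}, otherwise only the
#' highest-|loading| member of each correlated cluster survives (ties
#' broken lexicographically); (4) an indicator that qualifies on several
#' PCs is assigned to the PC where its |loading| is largest. PC-derived
#' weights are attached via [computeWeights()].
#'
#' @param pca a [PCAResult-class] from [pcaCorrelation()].
#' @param X the observations x indicators matrix the PCA was run on.
#' @param eigMin,varMinPct PC retention thresholds.
#' @param loadingWindow,loadingFloor candidate-loading thresholds.
#' @param rMax correlation-redundancy threshold.
#' @param splitWithinPC split a PC's weight equally among its selected
#'   indicators (default). \code{FALSE} gives each indicator its full PC
#'   weight, renormalised so the weights still sum to 1.
#' @return an [MDSSelection-class].
#' @export
selectMDS <- function(pca, X, eigMin = 0.9, varMinPct = 5,
                      loadingWindow = 0.10, loadingFloor = 0.40,
                      rMax = 0.60, splitWithinPC = TRUE) {
  X <- as.matrix(X)
  eig <- pca@eigenvalues
  retained <- which(eig >= eigMin & pca@variancePct > varMinPct)
  if (length(retained) == 0L)
    stop("empty selection: no PC passes the eigenvalue/variance rules")

  trace <- list()
  perPC <- lapply(retained, function(pc) {
    L <- pca@loadings[, pc]
    absL <- abs(L)
    cand <- names(absL)[absL >= (1 - loadingWindow) * max(absL) |
                          absL >= loadingFloor]
    cand <- cand[order(-absL[cand], cand)]
    kept <- cand
    rule <- setNames(rep("kept", length(cand)), cand)
    if (length(cand) > 1) {
      Rc <- abs(cor(X[, cand, drop = FALSE]))
      if (any(Rc[upper.tri(Rc)] >= rMax)) {
        # connected components of the |r| >= rMax graph; keep the
        # highest-|loading| member (lexicographic tie-break) per component
        comp <- seq_along(cand)
        for (i in seq_along(cand)) for (j in seq_along(cand))
          if (Rc[i, j] >= rMax && comp[j] != comp[i])
            comp[comp == comp[j]] <- comp[i]
        kept <- character(0)
        for (cc in unique(comp)) {
          members <- cand[comp == cc]
          best <- members[order(-absL[members], members)][1]
          kept <- c(kept, best)
          rule[setdiff(members, best)] <- "dropped_correlated"
        }
        kept <- cand[cand %in% kept]
      }
    }
    trace[[length(trace) + 1]] <<- data.frame(
      pc = paste0("PC", pc), indicator = cand,
      loading = L[cand], rule = rule[cand])
    kept
  })
  names(perPC) <- paste0("PC", retained)

  # rule (4): unique attribution by largest |loading|
  assignment <- character(0)
  for (pcLab in names(perPC)) {
    pc <- as.integer(sub("PC", "", pcLab))
    for (ind in perPC[[pcLab]]) {
      if (!ind %in% names(assignment)) {
        assignment[ind] <- pcLab
      } else {
        prev <- as.integer(sub("PC", "", assignment[ind]))
        if (abs(pca@loadings[ind, pc]) > abs(pca@loadings[ind, prev]))
          assignment[ind] <- pcLab
      }
    }
  }
  selected <- split(names(assignment), assignment)[unique(assignment)]
  selected <- selected[order(as.integer(sub("PC", "", names(selected))))]

  sel <- new("MDSSelection", retainedPCs = as.integer(retained),
             selectedIndicators = selected,
             weights = numeric(0), assignment = assignment,
             trace = do.call(rbind, trace))
  sel@weights <- computeWeights(pca, sel, splitWithinPC = splitWithinPC)
  validObject(sel)
  sel
}

#' PCA-derived indicator weights
#'
#' Each PC carrying at least one selected indicator receives weight
#' proportional to its variance percentage; with \code{splitWithinPC =
#' TRUE} (default) a PC's weight is divided equally among its indicators so
#' the weights sum to exactly 1. With \code{FALSE} every indicator inherits
#' its PC's full weight and the vector is renormalised to sum to 1.
#'
#' @param pca a [PCAResult-class].
#' @param selection an [MDSSelection-class].
#' @param splitWithinPC see Description.
#' @return named numeric weights, one per selected indicator, summing to 1.
#' @export
computeWeights <- function(pca, selection, splitWithinPC = TRUE) {
  selected <- selection@selectedIndicators
  if (!length(selected)) stop("selection is empty")
  pcIdx <- as.integer(sub("PC", "", names(selected)))
  vshare <- pca@variancePct[pcIdx]
  pcW <- vshare / sum(vshare)
  w <- unlist(mapply(function(inds, wpc) {
    if (splitWithinPC) setNames(rep(wpc / length(inds), length(inds)), inds)
    else setNames(rep(wpc, length(inds)), inds)
  }, selected, pcW, SIMPLIFY = FALSE), use.names = TRUE)
  names(w) <- unlist(selected, use.names = FALSE)
  w / sum(w)
}

#' Non-linear indicator scoring
#'
#' Sigmoid score \eqn{S = a / (1 + (x/x_0)^b)} with the slope's sign set by
#' the direction: negative for "more is better" (S increases with x),
#' positive for "less is better". At \eqn{x = x_0} the score is exactly
#' \eqn{a/2}.
#'
#' @param x positive observation value(s).
#' @param x0 positive baseline (by convention the indicator's grand mean
#'   over all observations).
#' @param b slope magnitude (default 2.5).
#' @param direction \code{"more_is_better"} or \code{"less_is_better"}.
#' @param a maximum of the scoring function (default 1).
#' @return score(s) in (0, a).
#' @examples
#' scoreNonlinear(2, 1, direction = "more_is_better")  # ~0.8498
#' @export
scoreNonlinear <- function(x, x0, b = 2.5,
                           direction = c("more_is_better",
                                         "less_is_better"),
                           a = 1) {
  direction <- match.arg(direction)
  if (any(x <= 0) || any(x0 <= 0))
    stop("scoring is defined for positive x and x0 only")
  bSigned <- if (direction == "more_is_better") -abs(b) else abs(b)
  a / (1 + (x / x0)^bSigned)
}

#' Default scoring directions for soil indicators
#'
#' "More is better" for every indicator except electrical conductivity
#' (salinity: "less is better").
#'
#' @param indicators indicator names.
#' @return named character vector of directions.
#' @export
defaultDirections <- function(indicators) {
  setNames(ifelse(indicators == "EC", "less_is_better", "more_is_better"),
           indicators)
}

#' Compute the soil quality index
#'
#' Scores every selected indicator per observation with
#' [scoreNonlinear()] and sums the weighted scores:
#' \eqn{SQI = \sum_i W_i S_i}. The baseline \eqn{x_0} of each indicator
#' defaults to its grand mean over all observations.
#'
#' @param soil replicate-level soil table.
#' @param selection an [MDSSelection-class] with weights.
#' @param directions named direction per indicator (default
#'   [defaultDirections()]).
#' @param b slope magnitude, scalar or named per indicator.
#' @param x0 optional named baselines; default grand means.
#' @return an [SQIResult-class].
#' @export
computeSQI <- function(soil, selection, directions = NULL, b = 2.5,
                       x0 = NULL) {
  inds <- unlist(selection@selectedIndicators, use.names = FALSE)
  missing <- setdiff(inds, colnames(soil))
  if (length(missing))
    stop("soil table lacks selected indicator column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(directions)) directions <- defaultDirections(inds)
  if (length(b) == 1L && is.null(names(b)))
    b <- setNames(rep(b, length(inds)), inds)
  if (is.null(x0))
    x0 <- vapply(inds, function(i) mean(soil[[i]]), numeric(1))
  w <- selection@weights[inds]
  scores <- vapply(inds, function(i)
    scoreNonlinear(soil[[i]], x0[[i]], b = b[[i]],
                   direction = directions[[i]]),
    numeric(nrow(soil)))
  if (nrow(soil) == 1L)
    scores <- matrix(scores, nrow = 1L, dimnames = list(NULL, inds))
  sqi <- as.numeric(scores %*% w)
  perScenario <- do.call(rbind, lapply(split(sqi, soil$scenario),
                                       function(v)
    data.frame(mean = mean(v), se = sd(v) / sqrt(length(v)),
               n = length(v))))
  perScenario <- data.frame(scenario = rownames(perScenario), perScenario,
                            row.names = NULL)
  params <- data.frame(indicator = inds, a = 1, b = unname(b[inds]),
                       x0 = unname(x0[inds]),
                       direction = unname(directions[inds]),
                       weight = unname(w))
  new("SQIResult", scores = scores, sqi = sqi, perScenario = perScenario,
      observations = soil, scoringParameters = params)
}

#' End-to-end soil quality index pipeline
#'
#' Chains significance screening, correlation PCA, minimum-data-set
#' selection, PCA weighting, non-linear scoring and the weighted index.
#'
#' @param soil replicate-level soil table.
#' @param alpha screening significance level.
#' @param useScenarioMeans run the PCA on scenario means instead of
#'   replicate-level observations (scoring always happens per observation).
#' @param directions,b passed to [computeSQI()].
#' @param ... thresholds passed to [selectMDS()].
#' @return list with elements \code{screen}, \code{pca}, \code{selection}
#'   and \code{sqi}.
#' @examples
#' soil <- simulateSoilTable(defaultStudySpecs(), seed = 1)
#' res <- sqiPipeline(soil)
#' res$sqi@perScenario
#' @export
sqiPipeline <- function(soil, alpha = 0.05, useScenarioMeans = FALSE,
                        directions = NULL, b = 2.5, ...) {
  screen <- screenIndicators(soil, alpha = alpha)
  if (!length(screen$retained))
    stop("no indicator passed the significance screen; ",
         "cannot build a minimum data set")
  X <- as.matrix(soil[, screen$retained, drop = FALSE])
  if (useScenarioMeans)
    X <- do.call(rbind, lapply(split(as.data.frame(X), soil$scenario),
                               colMeans))
  pca <- pcaCorrelation(X)
  selection <- selectMDS(pca, X, ...)
  sqi <- computeSQI(soil, selection, directions = directions, b = b)
  list(screen = screen, pca = pca, selection = selection, sqi = sqi)
}
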