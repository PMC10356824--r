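#' One-way ANOVA
#'
#' Standard between/within decomposition via \code{stats::lm}.
#'
#' @param values numeric response.
#' @param groups group label per value (>= 2 groups, each >= 2 values).
#' @return list with \code{F}, \code{p}, \code{MSE} and \code{dfError}.
#' @export
anovaOneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 values")
  if (var(values) == 0)
    stop("degenerate ANOVA: zero within-group variance (constant data)")
  fit <- lm(values ~ groups)
  a <- suppressWarnings(anova(fit))   # we flag perfect fits ourselves
  sst <- sum(a$`Sum Sq`)
  if (sst == 0 || a$`Mean Sq`[2] <= 1e-10 * sst / (length(values) - 1))
    stop("degenerate ANOVA: zero within-group variance")
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       MSE = a$`Mean Sq`[2], dfError = a$Df[2])
}

# Pairwise DMRT decisions on means sorted descending. A pair (i, j) is
# declared different iff for EVERY enclosing span (i', j') (including the
# pair's own span) the range mean[i'] - mean[j'] exceeds its critical range
# R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h), alpha_p = 1-(1-alpha)^(p-1).
.dmrtDecisions <- function(meansDesc, MSE, dfe, nh, alpha) {
  k <- length(meansDesc)
  Rp <- vapply(2:k, function(p) {
    qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, dfe) * sqrt(MSE / nh)
  }, numeric(1))
  spanSig <- function(i, j) (meansDesc[i] - meansDesc[j]) > Rp[j - i]
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- TRUE
    for (i2 in seq_len(i)) {
      for (j2 in j:k) {
        if (!spanSig(i2, j2)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    sig[i, j] <- sig[j, i] <- ok
  }
  sig
}

# Insert-and-absorb compact letter display. `sig` is a pairwise
# "significantly different" matrix over groups ordered descending by mean;
# letters are assigned starting at "a" for the largest mean.
.compactLetters <- function(sig, groupNames) {
  k <- length(groupNames)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (ci in rev(seq_along(cols))) {
      cc <- cols[[ci]]
      if (i %in% cc && j %in% cc) {
        cols[[ci]] <- NULL
        cols <- c(cols, list(setdiff(cc, i)), list(setdiff(cc, j)))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] %in% cols[[b]]) &&
          !(all(cols[[b]] %in% cols[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns by their first (highest-mean) member
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  lets <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(g)
    paste(lets[vapply(cols, function(cc) g %in% cc, logical(1))],
          collapse = ""),
    character(1))
  setNames(out, groupNames)
}

#' Duncan's multiple range test with compact letter display
#'
#' Means are sorted descending; the range over any span of p ordered means
#' is compared with the critical range
#' \eqn{R_p = q_{1-\alpha_p}(p, df_e) \sqrt{MSE / n}} at Duncan's
#' protection level \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}}, where q is the
#' studentized-range quantile. Two means differ iff their gap exceeds
#' \eqn{R_p} for their span and no enclosing span was declared
#' non-significant. Letters follow the convention that the largest mean is
#' lettered "a" and groups sharing any letter are indistinguishable.
#' Unequal group sizes use the harmonic mean of n (with a warning).
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level (default 0.05).
#' @return a [GroupComparisonResult-class].
#' @export
duncanMRT <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  aov1 <- anovaOneway(values, groups)
  if (aov1$dfError < 1) stop("error degrees of freedom < 1")
  ns <- c(tapply(values, groups, length))
  nh <- length(ns) / sum(1 / ns)
  if (length(unique(ns)) > 1)
    warning("unequal group sizes: harmonic mean n = ", round(nh, 3),
            " used in the critical ranges")
  mns <- c(tapply(values, groups, mean))
  ses <- c(tapply(values, groups, sd)) / sqrt(ns)
  ord <- order(-mns, names(mns))
  meansDesc <- mns[ord]
  sig <- .dmrtDecisions(meansDesc, aov1$MSE, aov1$dfError, nh, alpha)
  dimnames(sig) <- list(names(meansDesc), names(meansDesc))
  lets <- .compactLetters(sig, names(meansDesc))
  new("GroupComparisonResult", method = "anova_dmrt",
      statistic = aov1$F, pValue = aov1$p,
      groupMeans = mns, groupSE = ses, groupN = as.numeric(ns),
      letters = lets[names(mns)], decisions = sig, alpha = alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square (k - 1 df) p-value, via
#' \code{stats::kruskal.test}.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each >= 2 values).
#' @return list with \code{H} and \code{p}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 values")
  if (length(unique(values)) == 1)
    stop("all values identical: test undefined (all ties)")
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Pearson correlation with two-sided significance
#'
#' \eqn{r = cov(x, y)/(s_x s_y)} with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, via \code{stats::cor.test}.
#'
#' @param x,y numeric vectors (n >= 3, neither constant).
#' @return list with \code{r}, \code{p} and \code{n}.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Multi-column group comparison report
#'
#' Applies [duncanMRT()] or [kruskalWallis()] to each value column of a
#' table, producing the mean +/- SE + letter layout used for scenario
#' comparisons. (Kruskal-Wallis reports the omnibus verdict only; letters
#' come from the DMRT method.)
#'
#' @param table data.frame with a group column and value columns.
#' @param valueColumns columns to analyse; default all numeric columns
#'   except the group column.
#' @param groupColumn name of the grouping column.
#' @param method \code{"dmrt"} or \code{"kw"}.
#' @param alpha significance level.
#' @return data.frame: column, group, n, mean, SE, letter (DMRT),
#'   statistic, p.
#' @export
compareAll <- function(table, valueColumns = NULL, groupColumn = "scenario",
                       method = c("dmrt", "kw"), alpha = 0.05) {
  method <- match.arg(method)
  if (is.null(valueColumns))
    valueColumns <- setdiff(colnames(table)[vapply(table, is.numeric,
                                                   logical(1))],
                            c(groupColumn, "replicate"))
  g <- table[[groupColumn]]
  out <- lapply(valueColumns, function(v) {
    res <- tryCatch({
      if (method == "dmrt") {
        r <- duncanMRT(table[[v]], g, alpha = alpha)
        data.frame(column = v, group = names(r@groupMeans),
                   n = r@groupN, mean = unname(r@groupMeans),
                   se = unname(r@groupSE),
                   letter = unname(r@letters),
                   statistic = r@statistic, p = r@pValue)
      } else {
        r <- kruskalWallis(table[[v]], g)
        mns <- tapply(table[[v]], g, mean)
        ses <- tapply(table[[v]], g, sd) /
          sqrt(tapply(table[[v]], g, length))
        data.frame(column = v, group = names(mns),
                   n = as.numeric(tapply(table[[v]], g, length)),
                   mean = unname(mns), se = unname(ses),
                   letter = NA_character_,
                   statistic = r$H, p = r$p)
      }
    }, error = function(e) stop("column ", v, ": ",
                                conditionMessage(e)))
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
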