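# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (loops, enumeration, resampling) and never call the
# implementation they check.

# --- tiny scenario fixtures ------------------------------------------------

tinySpec <- function(id = "scX", class = "CA",
                     means = c(SOC = 9, pH = 7.2, EC = 0.2),
                     ses = c(SOC = 0.2, pH = 0.05, EC = 0.01),
                     comp = c(Proteobacteria = 0.5, Acidobacteria = 0.3,
                              Other = 0.2),
                     nSoil = 3L, nMicro = 3L) {
  scenarioSpec(id, class, soilMeans = means, soilSEs = ses,
               earthwormMean = 500, earthwormSE = 10,
               phylumComposition = comp, nSoilReps = nSoil,
               nMicrobiomeReps = nMicro)
}

# small OTU table built by hand (samples x OTUs)
tinyOTUTable <- function() {
  cm <- matrix(c(10L, 5L, 0L, 2L,
                 8L, 0L, 3L, 1L,
                 0L, 7L, 6L, 4L), nrow = 3, byrow = TRUE,
               dimnames = list(c("s1", "s2", "s3"),
                               c("o1", "o2", "o3", "o4")))
  tax <- data.frame(
    otu_id = c("o1", "o2", "o3", "o4"),
    lineage = c("k__Bacteria;p__Proteobacteria;c__Alpha;o__Rhizobiales;f__;g__",
                "k__Bacteria;p__Proteobacteria;c__Beta;o__Burkholderiales;f__;g__",
                "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__;g__",
                "k__Bacteria;p__;c__;o__;f__;g__"))
  meta <- data.frame(scenario = c("scI", "scI", "scIV"),
                     management = c("FP", "FP", "CA"),
                     row.names = c("s1", "s2", "s3"))
  makeOTUTable(cm, tax, meta)
}

# --- independent alpha-diversity oracles -----------------------------------

oracleShannon <- function(x) {
  x <- x[x > 0]; N <- sum(x); h <- 0
  for (c in x) h <- h - (c / N) * log(c / N)
  h
}

oracleSimpson <- function(x) {
  x <- x[x > 0]; N <- sum(x); s <- 0
  for (c in x) s <- s + (c / N)^2
  1 - s
}

oracleChao1 <- function(x) {
  x <- x[x > 0]
  length(x) + sum(x == 1) * (sum(x == 1) - 1) / (2 * (sum(x == 2) + 1))
}

# bisection on the defining equation S = a log(1 + N/a)
oracleFisher <- function(x, iters = 200) {
  x <- x[x > 0]; S <- length(x); N <- sum(x)
  lo <- 1e-9; hi <- 1e6
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid * log(1 + N / mid) < S) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# resampling oracle for rarefaction
oracleRarefy <- function(x, n, draws = 5000) {
  x <- x[x > 0]
  reads <- rep(seq_along(x), x)
  s <- vapply(seq_len(draws), function(i)
    length(unique(sample(reads, n))), numeric(1))
  c(mean = mean(s), se = sd(s) / sqrt(draws))
}

# --- ANOSIM oracles --------------------------------------------------------

oracleAnosimR <- function(D, groups) {
  n <- nrow(D)
  d <- c(); w <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- c(d, D[i, j]); w <- c(w, groups[i] == groups[j])
  }
  r <- rank(d); M <- length(d)
  (mean(r[!w]) - mean(r[w])) / (M / 2)
}

# all distinct relabelings of a two-group balanced design
allRelabelings <- function(groups) {
  g1 <- unique(groups)[1]
  n <- length(groups)
  k <- sum(groups == g1)
  idx <- utils::combn(n, k)
  lapply(seq_len(ncol(idx)), function(c) {
    g <- rep(unique(groups)[2], n); g[idx[, c]] <- g1; g
  })
}

# --- Duncan's MRT span-decision oracle -------------------------------------
# Step-down recursion: test the full span; a span whose range fails its
# critical value freezes every pair inside as non-significant; a passing
# span marks its endpoints different and recurses on both one-shorter
# subspans. Independent of the implementation's all-enclosing-spans rule.

oracleDMRT <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  fit <- stats::lm(values ~ groups)
  a <- stats::anova(fit)
  MSE <- a$`Mean Sq`[2]; dfe <- a$Df[2]
  ns <- tapply(values, groups, length)
  nh <- length(ns) / sum(1 / ns)
  mns <- sort(tapply(values, groups, mean), decreasing = TRUE)
  k <- length(mns)
  crit <- function(p) stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p,
                                    dfe) * sqrt(MSE / nh)
  sig <- matrix(NA, k, k, dimnames = list(names(mns), names(mns)))
  recurse <- function(i, j) {
    if (j <= i) return(invisible())
    if (!is.na(sig[i, j])) return(invisible())
    if ((mns[i] - mns[j]) > crit(j - i + 1)) {
      sig[i, j] <<- sig[j, i] <<- TRUE
      recurse(i, j - 1); recurse(i + 1, j)
    } else {
      for (a2 in i:(j - 1)) for (b2 in (a2 + 1):j)
        if (is.na(sig[a2, b2])) sig[a2, b2] <<- sig[b2, a2] <<- FALSE
    }
  }
  recurse(1, k)
  sig[is.na(sig)] <- FALSE
  diag(sig) <- FALSE
  sig
}

# --- planted-factor construction for MDS recovery --------------------------
# Two in-sample-orthogonal latent factors drive blocks of 3 and 2
# indicators (different block sizes keep the leading eigenvalues apart, so
# the PCs align with the blocks); success = the selection returns exactly
# one indicator per planted block.

plantedBlockRecovery <- function(seed, n = 60) {
  set.seed(seed)
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  f2 <- resid(lm(f2 ~ f1))            # orthogonalise in sample
  f1 <- scale(f1)[, 1]; f2 <- scale(f2)[, 1]
  # indicator noise residualised on both factors so the planted loading
  # pattern is realised in sample, not just in expectation
  E <- matrix(rnorm(n * 5), n, 5)
  E <- apply(E, 2, function(e) resid(lm(e ~ f1 + f2)))
  X <- cbind(a1 = f1 + 0.15 * E[, 1],
             a2 = f1 + 0.5 * E[, 2],
             a3 = f1 + 0.8 * E[, 3],
             b1 = f2 + 0.15 * E[, 4],
             b2 = f2 + 0.5 * E[, 5])
  sel <- tryCatch(selectMDS(pcaCorrelation(X), X, varMinPct = 5),
                  error = function(e) NULL)
  if (is.null(sel)) return(FALSE)
  inds <- unlist(sel@selectedIndicators, use.names = FALSE)
  length(inds) == 2 &&
    sum(startsWith(inds, "a")) == 1 && sum(startsWith(inds, "b")) == 1
}

# check a compact letter display against a pairwise decision matrix:
# (a) no two groups sharing a letter are declared different;
# (b) every non-different pair shares at least one letter.
cldConsistent <- function(letters, sig) {
  gs <- rownames(sig)
  for (i in seq_along(gs)[-length(gs)]) for (j in (i + 1):length(gs)) {
    shared <- length(intersect(strsplit(letters[gs[i]], "")[[1]],
                               strsplit(letters[gs[j]], "")[[1]])) > 0
    if (sig[gs[i], gs[j]] && shared) return(FALSE)
    if (!sig[gs[i], gs[j]] && !shared) return(FALSE)
  }
  TRUE
}
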