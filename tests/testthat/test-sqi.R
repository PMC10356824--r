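test_that("correlation PCA: duplicated variables, eigenvalue sum, signs", {
  set.seed(1)
  x <- rnorm(30)
  X2 <- cbind(a = x, b = 2 * x + 5)     # perfectly correlated pair
  p2 <- pcaCorrelation(X2)
  expect_equal(eigenvalues(p2), c(2, 0), tolerance = 1e-12)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, letters[1:6]))
  res <- pcaCorrelation(X)
  expect_equal(sum(eigenvalues(res)), 6, tolerance = 1e-9)
  expect_equal(sum(variancePct(res)), 100, tolerance = 1e-9)
  L <- loadings2(res)
  expect_true(all(abs(L) <= 1 + 1e-9))
  for (k in 1:6) expect_gt(L[which.max(abs(L[, k])), k], 0)
  # loading = eigenvector * sqrt(eigenvalue): squared loadings per PC sum
  # to the eigenvalue
  expect_equal(colSums(L^2), eigenvalues(res), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pcaCorrelation(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
  expect_error(pcaCorrelation(X[1:2, ]), "at least 3")
})

test_that("independent variables yield near-unit eigenvalues at large n", {
  set.seed(2)
  X <- matrix(rnorm(4000 * 5), 4000, 5)
  ev <- eigenvalues(pcaCorrelation(X))
  # Marchenko-Pastur half-width ~ 2*sqrt(p/n) ~ 0.07
  expect_true(all(abs(ev - 1) < 0.15))
})

test_that("variance percentages follow eigenvalue/p * 100", {
  vp <- pcaVariancePct(c(7.75, 5.26, 3.68, 2.52), p = 21)
  expect_equal(vp, c(7.75, 5.26, 3.68, 2.52) / 21 * 100)
  expect_error(pcaVariancePct(c(-1, 2), 21), "non-negative")
})

test_that("significance screen keeps real contrasts, drops pure noise", {
  set.seed(3)
  # two scenarios 10 SDs apart: always retained
  soil <- data.frame(sample_id = paste0("s", 1:6),
                     scenario = rep(c("sc1", "sc2"), each = 3),
                     replicate = rep(1:3, 2),
                     strong = c(rnorm(3, 0), rnorm(3, 10)),
                     noise = rnorm(6))
  sc <- screenIndicators(soil, alpha = 0.05)
  expect_true("strong" %in% sc$retained)
  # null indicator excluded at alpha = 0.05 in >= 93% of simulations
  hits <- vapply(1:300, function(i) {
    set.seed(i)
    d <- data.frame(scenario = rep(paste0("sc", 1:4), each = 3),
                    x = rnorm(12))
    "x" %in% screenIndicators(d, indicators = "x")$retained
  }, logical(1))
  expect_lte(mean(hits), 0.07)
  # zero-variance indicator: warned and retained
  soil$flat <- rep(1, 6)
  expect_warning(sc2 <- screenIndicators(soil), "retained")
  expect_true("flat" %in% sc2$retained)
})

test_that("MDS selection: dominant indicator, duplicate collapse, rules", {
  set.seed(4)
  # one latent factor, a dominant indicator tracking it tightly plus a
  # strongly correlated shadow: the redundancy rule must leave exactly
  # the dominant one on PC1. Noise directions are built orthonormal to
  # the factor and to each other so the planted loading order is realised
  # in sample, not just in expectation.
  Q <- qr.Q(qr(cbind(rnorm(40), matrix(rnorm(40 * 4), 40, 4))))
  f <- Q[, 1]
  X <- cbind(dominant = f + 0.05 * Q[, 2],
             shadow = f + 0.8 * Q[, 3],
             n1 = Q[, 4], n2 = Q[, 5])
  pca <- pcaCorrelation(X)
  sel <- selectMDS(pca, X, varMinPct = 5)
  expect_identical(sel@selectedIndicators[["PC1"]], "dominant")
  # exact copies both load on PC1; correlation rule keeps exactly one
  Y <- cbind(a = f, b = f, c = rnorm(40))
  pcaY <- pcaCorrelation(Y)
  selY <- selectMDS(pcaY, Y)
  expect_length(selY@selectedIndicators[["PC1"]], 1L)
  expect_true(any(selY@trace$rule == "dropped_correlated"))
  # no PC passes: empty-selection error
  expect_error(selectMDS(pcaY, Y, eigMin = 10), "empty selection")
  # a four-PC spectrum with eigenvalues like 7.75/5.26/3.68/2.52 on p = 21
  # retains all four PCs under (0.9, 5%)
  ev <- c(7.75, 5.26, 3.68, 2.52)
  keep <- which(ev >= 0.9 & pcaVariancePct(ev, 21) > 5)
  expect_equal(keep, 1:4)
})

test_that("planted-block MDS recovery succeeds in >= 95% of seeds", {
  recovered <- vapply(1:50, plantedBlockRecovery, logical(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("weights derive from PC variance shares and sum to one", {
  # two PCs at 40% and 10% variance, one indicator each -> 0.8 / 0.2
  ev <- c(4, 1, rep(5 / 8, 8))   # 40%, 10%, remainder spread evenly
  pca <- new("PCAResult", eigenvalues = ev,
             variancePct = ev / 10 * 100,
             cumulativePct = cumsum(ev / 10 * 100),
             loadings = matrix(0, 10, 10,
                               dimnames = list(paste0("v", 1:10), NULL)),
             variableNames = paste0("v", 1:10))
  sel <- new("MDSSelection", retainedPCs = c(1L, 2L),
             selectedIndicators = list(PC1 = "v1", PC2 = "v2"),
             weights = numeric(0),
             assignment = c(v1 = "PC1", v2 = "PC2"),
             trace = data.frame())
  w <- computeWeights(pca, sel)
  expect_equal(w, c(v1 = 0.8, v2 = 0.2))
  # splitting within a PC keeps the total at 1
  sel2 <- sel
  sel2@selectedIndicators <- list(PC1 = c("v1", "v3"), PC2 = "v2")
  sel2@assignment <- c(v1 = "PC1", v3 = "PC1", v2 = "PC2")
  w2 <- computeWeights(pca, sel2)
  expect_equal(sum(w2), 1)
  expect_equal(unname(w2["v1"]), unname(w2["v3"]))
  w3 <- computeWeights(pca, sel2, splitWithinPC = FALSE)
  expect_equal(sum(w3), 1)
  expect_gt(w3[["v1"]], w2[["v1"]])
})

test_that("non-linear scoring: midpoint, limits, monotonicity", {
  for (b in c(1, 2.5, 7))
    expect_equal(scoreNonlinear(3.3, 3.3, b = b), 0.5)
  expect_equal(scoreNonlinear(1e9, 1, direction = "more_is_better"), 1,
               tolerance = 1e-3)
  expect_lt(scoreNonlinear(1e-9, 1, direction = "more_is_better"), 1e-3)
  expect_equal(scoreNonlinear(2, 1, b = 2.5, "more_is_better"),
               1 / (1 + 2^-2.5), tolerance = 1e-12)   # ~0.8498
  grid <- seq(0.1, 5, by = 0.1)
  sMore <- scoreNonlinear(grid, 1.7, direction = "more_is_better")
  expect_true(all(diff(sMore) > 0))
  sLess <- scoreNonlinear(grid, 1.7, direction = "less_is_better")
  expect_true(all(diff(sLess) < 0))
  expect_true(all(sMore > 0 & sMore < 1))
  expect_error(scoreNonlinear(-1, 1), "positive")
  expect_error(scoreNonlinear(1, 0), "positive")
})

test_that("SQI: weighting identities, monotonicity, invariances", {
  soil <- simulateSoilTable(defaultStudySpecs(), seed = 10)
  res <- sqiPipeline(soil)
  w <- res$selection@weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(res$sqi@sqi > 0 & res$sqi@sqi < 1))
  # x = x0 for every indicator -> SQI exactly 0.5
  inds <- unlist(res$selection@selectedIndicators, use.names = FALSE)
  soilMid <- soil
  for (i in inds) soilMid[[i]] <- mean(soil[[i]])
  resMid <- computeSQI(soilMid, res$selection,
                       x0 = vapply(inds, function(i) mean(soil[[i]]),
                                   numeric(1)))
  expect_equal(unique(round(resMid@sqi, 12)), 0.5)
  # row-order and label invariance
  perm <- sample(nrow(soil))
  resPerm <- computeSQI(soil[perm, ], res$selection)
  expect_equal(resPerm@sqi, res$sqi@sqi[perm])
  relab <- soil
  relab$scenario <- chartr("IV", "XY", relab$scenario)
  resRelab <- computeSQI(relab, res$selection)
  expect_equal(sort(resRelab@perScenario$mean),
               sort(res$sqi@perScenario$mean))
  # uniformly larger "more is better" values -> strictly larger SQI
  soilHi <- soil
  for (i in setdiff(inds, "EC")) soilHi[[i]] <- soil[[i]] * 1.5
  resHi <- computeSQI(soilHi, res$selection,
                      x0 = vapply(inds, function(i) mean(soil[[i]]),
                                  numeric(1)))
  if (length(setdiff(inds, "EC")))
    expect_true(all(resHi@sqi > res$sqi@sqi))
  expect_error(computeSQI(soil[, 1:4], res$selection), "lacks")
})

test_that("sqiPipeline chains the stages it reports", {
  soil <- simulateSoilTable(defaultStudySpecs(), seed = 15)
  res <- sqiPipeline(soil)
  X <- as.matrix(soil[, res$screen$retained])
  manual <- pcaCorrelation(X)
  expect_equal(eigenvalues(res$pca), eigenvalues(manual))
  manualSel <- selectMDS(manual, X)
  expect_equal(manualSel@weights, res$selection@weights)
  manualSQI <- computeSQI(soil, manualSel)
  expect_equal(manualSQI@sqi, res$sqi@sqi)
  res2 <- sqiPipeline(soil)
  expect_equal(res2$sqi@sqi, res$sqi@sqi)   # deterministic
})
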