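test_that("one-way ANOVA matches hand-computed sums of squares", {
  # textbook-style fixed vectors
  v <- c(6, 8, 4, 5, 3, 4, 6, 2, 10, 8, 11, 7)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  Fhand <- (ssb / 2) / (ssw / 9)
  res <- anovaOneway(v, g)
  expect_equal(res$F, Fhand, tolerance = 1e-12)
  expect_equal(res$MSE, ssw / 9, tolerance = 1e-12)
  expect_equal(res$dfError, 9)
  expect_equal(res$p, pf(Fhand, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  # two groups 10 SDs apart at n = 3: decisive
  set.seed(2)
  a <- rnorm(3, 0, 1); b <- rnorm(3, 10, 1)
  expect_lt(anovaOneway(c(a, b), rep(c("A", "B"), each = 3))$p, 0.01)
  expect_error(anovaOneway(c(1, 1, 2, 2), c("A", "A", "B", "B")),
               "degenerate")
  expect_error(anovaOneway(1:3, c("A", "A", "B")), ">= 2 values")
})

test_that("null F averages df2/(df2-2) over simulations", {
  set.seed(5)
  Fs <- vapply(1:800, function(i)
    anovaOneway(rnorm(20), rep(1:4, each = 5))$F, numeric(1))
  df2 <- 16
  expect_equal(mean(Fs), df2 / (df2 - 2), tolerance = 0.1)
})

test_that("DMRT separates distant means and letters match convention", {
  set.seed(9)
  base <- rnorm(5)
  v <- c(base, base + 20)   # ~20 residual SDs apart
  g <- rep(c("low", "high"), each = 5)
  res <- duncanMRT(v, g)
  expect_equal(unname(groupLetters(res)[c("high", "low")]), c("a", "b"))
  # three well-separated groups: a, b, c in descending-mean order
  v3 <- c(rnorm(4, 0), rnorm(4, 30), rnorm(4, 60))
  g3 <- rep(c("lo", "mid", "hi"), each = 4)
  r3 <- duncanMRT(v3, g3)
  expect_equal(unname(groupLetters(r3)[c("hi", "mid", "lo")]),
               c("a", "b", "c"))
})

test_that("identically drawn groups share a single letter at the
          protected rate", {
  # two groups: the full-span protection level is alpha itself, so a
  # single shared letter is expected in ~95% of null draws (for k groups
  # Duncan's design only protects at (1-alpha)^(k-1))
  set.seed(27)
  single <- vapply(1:200, function(i) {
    v <- rnorm(10)
    r <- duncanMRT(v, rep(c("A", "B"), each = 5))
    length(unique(groupLetters(r))) == 1
  }, logical(1))
  expect_gte(mean(single), 0.9)
})

test_that("DMRT decisions equal the step-down span oracle on random data", {
  set.seed(17)
  for (i in 1:200) {
    k <- sample(3:6, 1)
    n <- sample(3:5, 1)
    effects <- rnorm(k, sd = sample(c(0, 1, 3), 1))
    v <- rnorm(k * n) + rep(effects, each = n)
    g <- rep(paste0("g", seq_len(k)), each = n)
    res <- duncanMRT(v, g)
    oracle <- oracleDMRT(v, g)
    expect_equal(res@decisions[rownames(oracle), colnames(oracle)],
                 oracle)
    expect_true(cldConsistent(groupLetters(res), res@decisions))
  }
})

test_that("DMRT uses the harmonic mean for unequal group sizes", {
  set.seed(4)
  v <- c(rnorm(3), rnorm(5, 10), rnorm(4, 20))
  g <- c(rep("a", 3), rep("b", 5), rep("c", 4))
  expect_warning(res <- duncanMRT(v, g), "harmonic mean")
  expect_true(cldConsistent(groupLetters(res), res@decisions))
})

test_that("Kruskal-Wallis: hand-ranked example and tie correction", {
  # fully separated ranks, n = (3, 3): H = 12/(6*7)*(3*2^2+3*5^2)-3*7
  v <- c(1.1, 2.2, 3.3, 7.7, 8.8, 9.9)
  g <- rep(c("A", "B"), each = 3)
  res <- kruskalWallis(v, g)
  Hhand <- 12 / (6 * 7) * (3 * 2^2 + 3 * 5^2) - 3 * 7
  expect_equal(res$H, Hhand, tolerance = 1e-12)
  expect_equal(res$p, pchisq(Hhand, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # no ties: tie-correction factor exactly 1, so H matches the raw formula
  v2 <- c(3, 1, 4, 15, 9, 2, 6, 5)
  g2 <- rep(c("A", "B"), each = 4)
  r <- rank(v2); N <- 8
  Hraw <- 12 / (N * (N + 1)) *
    sum(tapply(r, g2, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  expect_equal(kruskalWallis(v2, g2)$H, Hraw, tolerance = 1e-12)
  # with ties the divisor 1 - sum(t^3 - t)/(N^3 - N) applies
  v3 <- c(1, 2, 2, 3, 4, 4, 4, 5)
  tie <- table(v3[duplicated(v3) | duplicated(v3, fromLast = TRUE)])
  r3 <- rank(v3)
  Hraw3 <- 12 / (8 * 9) *
    sum(tapply(r3, g2, function(x) sum(x)^2 / length(x))) - 3 * 9
  corr <- 1 - sum(sapply(as.integer(table(v3)),
                         function(t) t^3 - t)) / (8^3 - 8)
  expect_equal(kruskalWallis(v3, g2)$H, Hraw3 / corr, tolerance = 1e-12)
  expect_error(kruskalWallis(rep(1, 6), g), "ties")
})

test_that("Pearson correlation: affine, orthogonal, manual oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(8)
  y <- rnorm(20); z <- rnorm(20)
  resid <- z - sum(z * (y - mean(y))) /
    sum((y - mean(y))^2) * (y - mean(y))
  resid <- resid - mean(resid)
  expect_lt(abs(pearsonCorrelation(y, resid + mean(z))$r), 1e-12)
  a <- c(2.3, 4.1, 1.7, 5.5, 3.2, 6.8, 2.9)
  b <- c(1.0, 3.5, 2.2, 4.9, 2.8, 6.1, 3.3)
  rHand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- pearsonCorrelation(a, b)
  expect_equal(res$r, rHand, tolerance = 1e-12)
  tHand <- rHand * sqrt(5 / (1 - rHand^2))
  expect_equal(res$p, 2 * pt(abs(tHand), 5, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("Pearson p-value agrees with a permutation p at small n", {
  set.seed(23)
  x <- rnorm(8); y <- 0.6 * x + rnorm(8, sd = 0.8)
  res <- pearsonCorrelation(x, y)
  B <- 4000
  permR <- vapply(seq_len(B), function(i)
    abs(cor(x, sample(y))), numeric(1))
  pPerm <- (1 + sum(permR >= abs(res$r))) / (B + 1)
  expect_lt(abs(res$p - pPerm), 4 * sqrt(pPerm * (1 - pPerm) / B) + 0.01)
})

test_that("compareAll reproduces per-column analyses", {
  soil <- simulateSoilTable(defaultStudySpecs(), seed = 6)
  rep1 <- compareAll(soil, valueColumns = c("SOC", "K"),
                     groupColumn = "scenario", method = "dmrt")
  expect_setequal(unique(rep1$column), c("SOC", "K"))
  direct <- duncanMRT(soil$SOC, soil$scenario)
  sub <- rep1[rep1$column == "SOC", ]
  expect_equal(setNames(sub$letter, sub$group),
               groupLetters(direct)[sub$group])
  expect_identical(rep1, compareAll(soil, valueColumns = c("SOC", "K"),
                                    groupColumn = "scenario",
                                    method = "dmrt"))
  rep2 <- compareAll(soil, valueColumns = "SOC", groupColumn = "scenario",
                     method = "kw")
  expect_equal(unique(rep2$statistic),
               kruskalWallis(soil$SOC, soil$scenario)$H)
})
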