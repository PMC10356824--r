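test_that("Shannon index: closed forms, oracle, and error cases", {
  expect_equal(shannonIndex(c(10, 0, 0)), 0)
  expect_equal(shannonIndex(c(5, 5, 5, 5)), log(4))
  expect_equal(shannonIndex(c(4, 3, 2, 1)), oracleShannon(c(4, 3, 2, 1)),
               tolerance = 1e-12)
  expect_error(shannonIndex(c(0, 0)), "empty sample")
  expect_error(shannonIndex(c(-1, 2)), "non-negative")
})

test_that("Gini-Simpson: closed forms, finite-sample variant, oracle", {
  expect_equal(simpsonIndex(7), 0)
  expect_equal(simpsonIndex(rep(3, 6)), 1 - 1 / 6)
  expect_equal(simpsonIndex(c(4, 3, 2, 1)), oracleSimpson(c(4, 3, 2, 1)),
               tolerance = 1e-12)
  x <- c(4, 3, 2, 1); N <- 10
  expect_equal(simpsonIndex(x, finiteSample = TRUE),
               1 - sum(x * (x - 1)) / (N * (N - 1)))
  expect_error(simpsonIndex(c(0, 0)), "empty sample")
})

test_that("Chao1: F1 = 0 case, formula example, classic variant", {
  expect_equal(chao1(c(5, 5, 3)), 3)                 # no singletons
  x <- c(rep(5, 5), 1, 1, 1, 2, 2)                   # S=10, F1=3, F2=2
  expect_equal(chao1(x), 10 + 3 * 2 / (2 * 3))       # 11
  expect_equal(chao1(x, biasCorrected = FALSE), 10 + 9 / 4)
  expect_equal(chao1(c(1, 1, 2, 3), biasCorrected = FALSE),
               4 + 4 / 2)                            # classic F2>0 path
  # F2 = 0 handled by the bias-corrected denominator
  expect_equal(chao1(c(1, 1, 5)), 3 + 2 * 1 / 2)
})

test_that("ACE: abundant-only, gamma clamp, singleton fallback", {
  expect_equal(ace(c(20, 30, 40)), 3)                # all abundant
  even <- rep(4, 8)                                  # raw gamma^2 < 0
  expect_equal(ace(even), 8)                         # S_rare/C = 8, F1 = 0
  expect_warning(res <- ace(c(1, 1, 1, 50)), "falling back to Chao1")
  expect_equal(res, chao1(c(1, 1, 1, 50)))
})

test_that("Fisher's alpha: identity, monotonicity, bisection oracle", {
  x <- c(rep(1, 40), rep(2, 30), rep(5, 20), rep(50, 10))
  a <- fisherAlpha(x)
  S <- sum(x > 0); N <- sum(x)
  expect_lt(abs(a * log(1 + N / a) - S), 1e-8)       # defining identity
  # S = 100, N = 10,000, vs an independent bisection
  y <- c(rep(99, 99), 10000 - 99 * 99)
  expect_equal(fisherAlpha(y), oracleFisher(y), tolerance = 1e-6)
  # for fixed N, alpha increases with S
  alphas <- vapply(c(10, 20, 40, 80), function(S0) {
    v <- c(rep(1, S0 - 1), 1000 - (S0 - 1))
    fisherAlpha(v)
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
  expect_error(fisherAlpha(rep(1, 5)), "diverges")
  expect_error(fisherAlpha(c(0, 0)), "empty sample")
})

test_that("observed richness matches a naive loop", {
  expect_equal(observedOTUs(c(0, 0, 1)), 1)
  expect_equal(observedOTUs(rep(0, 4)), 0)
  set.seed(1)
  x <- rpois(200, 1)
  naive <- 0; for (v in x) if (v > 0) naive <- naive + 1
  expect_equal(observedOTUs(x), naive)
})

test_that("estimators equal independent references on 100 random vectors", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (i in 1:100) {
    x <- rpois(80, exp(rnorm(1, 1, 0.8)))
    if (sum(x) == 0) x[1] <- 1
    xp <- x[x > 0]
    er <- vegan::estimateR(xp)
    expect_equal(shannonIndex(x), oracleShannon(x), tolerance = 1e-8)
    expect_equal(simpsonIndex(x), oracleSimpson(x), tolerance = 1e-8)
    expect_equal(chao1(x), unname(er["S.chao1"]), tolerance = 1e-8)
    expect_equal(chao1(x), oracleChao1(x), tolerance = 1e-8)
    nRare <- sum(xp <= 10)
    if (nRare > 0 && sum(xp == 1) < nRare)
      expect_equal(ace(x), unname(er["S.ACE"]), tolerance = 1e-8)
    if (length(xp) < sum(xp))
      expect_equal(fisherAlpha(x), vegan::fisher.alpha(xp),
                   tolerance = 1e-6)
  }
})

test_that("richness estimators dominate observed richness", {
  set.seed(7)
  for (i in 1:50) {
    x <- rpois(100, 0.8); if (sum(x) == 0) x[1] <- 2
    s <- observedOTUs(x)
    expect_gte(chao1(x), s)
    rare <- x[x > 0 & x <= 10]
    if (length(rare) && sum(rare == 1) < length(rare))
      expect_gte(ace(x) + 1e-9, s)
  }
})

test_that("Shannon is bounded by log richness with equality iff uniform", {
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(30, 3) + 1
    expect_lte(shannonIndex(x), log(observedOTUs(x)) + 1e-12)
  }
  expect_equal(shannonIndex(rep(9, 12)), log(12))
  expect_lt(shannonIndex(c(9, 9, 1)), log(3) - 1e-6)
})

test_that("rarefaction: exact endpoints, monotone concave, oracle", {
  x <- c(20, 10, 5, 3, 1, 1)
  N <- sum(x)
  rc <- rarefactionCurve(x, c(1, seq(5, N, by = 5), N))
  expect_equal(rc$expected_richness[1], 1)
  expect_equal(rc$expected_richness[nrow(rc)], observedOTUs(x))
  d1 <- diff(rc$expected_richness)
  expect_true(all(d1 > -1e-12))                      # non-decreasing
  grid <- rarefactionCurve(x, 1:N)$expected_richness
  expect_true(all(diff(diff(grid)) < 1e-9))          # concave
  expect_error(rarefactionCurve(x, N + 1), "invalid depth")
  # resampling oracle
  set.seed(11)
  mc <- oracleRarefy(x, 15, draws = 5000)
  expect_lt(abs(rarefactionCurve(x, 15)$expected_richness - mc["mean"]),
            4 * mc["se"] + 1e-9)
})

test_that("alphaTable composes the per-sample estimators", {
  tab <- tinyOTUTable()
  a <- alphaTable(tab)
  expect_equal(nrow(a), 3L)
  cnt <- otuCounts(tab)[, "s1"]
  expect_equal(a$shannon[a$sample_id == "s1"], shannonIndex(cnt))
  expect_equal(a$chao1[a$sample_id == "s1"], chao1(cnt))
  expect_identical(a, alphaTable(tab))               # deterministic
  s <- alphaSummary(a)
  expect_equal(s$n, c(2L, 1L))
  expect_equal(s$shannon_mean[s$scenario == "scI"],
               mean(a$shannon[a$scenario == "scI"]))
})

test_that("Chao1 recovers a known OTU pool at saturating depth", {
  # Dirichlet-multinomial samples over a pool flat enough that every OTU
  # is observable: mean Chao1 within 10% of the true pool size.
  sp <- tinySpec(comp = c(Proteobacteria = 0.4, Acidobacteria = 0.35,
                          Other = 0.25), nMicro = 5L)
  tab <- simulateOTUTable(list(sp), nOTUsPerPhylum = 40L, depth = 100000,
                          theta = 500, geomRatio = 0.95, seed = 21)
  truth <- nrow(tab)   # 3 phyla x 40 OTUs
  ch <- apply(otuCounts(tab), 2, chao1)
  expect_lt(abs(mean(ch) - truth) / truth, 0.10)
})
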