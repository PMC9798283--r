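test_that("rank-sum z matches exact enumeration for disjoint small samples", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- ranksumZ(x, y)
  # brute-force permutation oracle: all C(6,3) = 20 rank assignments
  allRanks <- combn(6, 3)
  Wnull <- colSums(allRanks)
  Wobs <- sum(rank(c(x, y))[1:3])
  pExact <- mean(abs(Wnull - mean(Wnull)) >= abs(Wobs - mean(Wnull)))
  expect_equal(pExact, 0.1)                     # 2 extreme splits / 20, 2-tail
  # normal approximation should agree with the exact tail to ~0.02 here
  expect_lt(res$z, 0)                           # x below y
  expect_lt(abs(res$p - pExact), 0.03)
  expect_equal(res$n, 6)
})

test_that("rank-sum is antisymmetric and null on identical samples", {
  set.seed(4)
  x <- rnorm(12); y <- rnorm(15)
  a <- ranksumZ(x, y); b <- ranksumZ(y, x)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  same <- ranksumZ(x, x)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(ranksumZ(numeric(0), y), "non-empty")
  # agreement with the standard implementation on continuous data
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(a$p, ref$p.value, tolerance = 0.02)
  # invariance under strictly monotone transforms (rank-based)
  expect_equal(ranksumZ(exp(x), exp(y))$z, a$z)
})

test_that("Rosenthal effect size is z over root n", {
  expect_equal(rosenthalEffectSize(0, 50), 0)
  expect_equal(rosenthalEffectSize(2.32, 116), 2.32 / sqrt(116))
  expect_equal(rosenthalEffectSize(1.5, 200),
               rosenthalEffectSize(1.5, 100) / sqrt(2))
  expect_error(rosenthalEffectSize(1, 0), ">= 1")
})

test_that("signed-rank test matches the exact distribution at small n", {
  x <- c(10, 12, 9, 14, 11, 13)
  y <- x + c(1, 2, 3, 4, 5, 6) * 0.5            # distinct positive shifts
  res <- signedRankTest(y, x)
  expect_gt(res$z, 0)
  # exact one-sided p for the maximal statistic is 2^-6; two-tailed doubles it
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value
  expect_equal(ref, 2 / 64)
  expect_lt(res$p, 0.1)                         # small for n = 6
  expect_error(signedRankTest(1, 2), "at least 2")
  expect_error(signedRankTest(x, x), "all differences are zero")
})

test_that("signed-rank p is roughly uniform under the paired null", {
  set.seed(7)
  ps <- replicate(300, {
    d <- rnorm(25)
    signedRankTest(d, rep(0, 25))$p
  })
  expect_gt(mean(ps < 0.5), 0.42)
  expect_lt(mean(ps < 0.5), 0.58)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.05)
})

test_that("Kruskal-Wallis reproduces hand rank arithmetic and handles ties", {
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(6, 7, 8, 9, 10); g3 <- c(11, 12, 13, 14, 15)
  res <- kruskalTest(list(g1, g2, g3))
  # independent rank-arithmetic oracle (no ties): H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1)
  Rsums <- c(sum(1:5), sum(6:10), sum(11:15))
  H <- 12 / (15 * 16) * sum(Rsums^2 / 5) - 3 * 16
  expect_equal(res$H, H)
  expect_equal(res$df, 2)
  expect_lt(res$p, 0.01)
  const <- kruskalTest(list(rep(1, 4), rep(1, 5)))
  expect_equal(const$H, 0)
  expect_equal(const$p, 1)
  expect_error(kruskalTest(list(g1)), "two groups")
  expect_error(kruskalTest(list(g1, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis p is calibrated under permutation of labels", {
  set.seed(11)
  ps <- replicate(200, {
    v <- rnorm(30)
    g <- split(v, sample(rep(1:3, 10)))
    kruskalTest(g)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroniAdjust(0.01, 5), 0.05)
  expect_equal(bonferroniAdjust(0.5, 4), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.03)), c(0.4, 0.06))
  expect_equal(bonferroniAdjust(0.3, 1), 0.3)
  expect_error(bonferroniAdjust(c(0.1, 0.2), 1), ">=")
})

test_that("Gaussian smoothing preserves constants and impulse mass", {
  m <- matrix(4.2, 9, 7)
  expect_equal(gaussianSmooth2D(m, 3), m, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussianSmooth2D(imp, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-10)          # mass conserved
  expect_equal(which.max(sm), which.max(imp))          # centred
  expect_error(gaussianSmooth2D(m, 0), "positive")
})

test_that("smoothing shrinks white-noise variance by the kernel energy", {
  fwhm <- 3
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  radius <- ceiling(4 * sigma)
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2)); k <- k / sum(k)
  k2 <- outer(k, k)
  shrink <- sum(k2^2)                                  # theoretical factor
  set.seed(5)
  ratios <- replicate(40, {
    m <- matrix(rnorm(60 * 60), 60)
    sm <- gaussianSmooth2D(m, fwhm)
    var(as.vector(sm[15:45, 15:45]))                   # interior only
  })
  expect_equal(mean(ratios), shrink, tolerance = 0.1)
})

test_that("random-field threshold is monotone and hits the pointwise limit", {
  u1 <- rftThreshold(c(30, 30), 3, 0.01)
  u2 <- rftThreshold(c(30, 30), 3, 0.05)
  u3 <- rftThreshold(c(30, 30), 3, 0.2)
  expect_true(u1 > u2 && u2 > u3)
  # huge smoothness: one resel -> two-tail pointwise Gaussian quantile
  uLim <- rftThreshold(c(10, 10), 1e6, 0.05)
  expect_equal(uLim, qnorm(1 - 0.025), tolerance = 1e-3)
  expect_error(rftThreshold(c(1, 5), 3, 0.05), "degenerate")
  expect_error(rftThreshold(c(10, 10), 3, 1.5), "alpha")
})

test_that("chi-square normality test flags bimodality and calibrates on normals", {
  set.seed(13)
  power <- mean(replicate(60, {
    x <- c(rnorm(100, -4), rnorm(100, 4))
    chisqNormalityTest(x)$p < 0.05
  }))
  expect_gte(power, 0.95)
  ps <- replicate(200, chisqNormalityTest(rnorm(200))$p)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.06)
  expect_error(chisqNormalityTest(rep(1, 50)), "zero variance")
  expect_error(chisqNormalityTest(rnorm(10)), "at least 20")
})
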