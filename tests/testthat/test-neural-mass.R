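test_that("population sigmoids hit their closed-form landmarks", {
  p <- neuralMassParams()
  expect_equal(sigmoidE(6, p), 50)                       # half-maximum at v0
  expect_equal(sigmoidE(1e6, p), 100, tolerance = 1e-12) # saturates at Fe
  expect_equal(sigmoidE(6 + log(3) / 0.56, p), 75, tolerance = 1e-12)
  expect_equal(sigmoidI(6, p), 25)                       # Fi/2
  v <- seq(-20, 30, 0.5)
  expect_true(all(diff(sigmoidE(v, p)) > 0))             # strictly increasing
  expect_true(all(sigmoidE(v, p) > 0 & sigmoidE(v, p) < 100))
})

test_that("coupling weights are streamline counts over the mean count", {
  sc <- matrix(0, 3, 3)
  sc[upper.tri(sc)] <- c(2, 4, 6)  # off-diagonal counts {2,2,4,4,6,6}
  sc <- sc + t(sc)
  pl <- (sc > 0) * 50
  conn <- new("StructuralConnectome", sc = sc, pl = pl)
  cw <- couplingFromSC(conn)
  expect_equal(cw$W, 4)
  expect_equal(sort(cw$cnm[upper.tri(cw$cnm)]), c(0.5, 1, 1.5))
  expect_equal(diag(cw$cnm), rep(0, 3))
  # all-equal counts give unit weights; doubling counts changes nothing
  scEq <- matrix(7, 3, 3); diag(scEq) <- 0
  connEq <- new("StructuralConnectome", sc = scEq, pl = (scEq > 0) * 10)
  expect_equal(couplingFromSC(connEq)$cnm, (scEq > 0) * 1)
  conn2 <- new("StructuralConnectome", sc = 2 * sc, pl = pl)
  expect_equal(couplingFromSC(conn2)$cnm, cw$cnm)
  empty <- new("StructuralConnectome", sc = matrix(0, 2, 2),
               pl = matrix(0, 2, 2))
  expect_error(couplingFromSC(empty), "empty")
})

test_that("delays scale path lengths by the global delay in s/m", {
  pl <- matrix(c(0, 100, 100, 0), 2, 2)
  expect_equal(delaysFromPL(pl, 0.1)[1, 2], 0.01)  # 100 mm at 0.1 s/m
  expect_equal(delaysFromPL(pl, 0), matrix(0, 2, 2))
  expect_error(delaysFromPL(pl, -1), "non-negative")
  expect_equal(feasibleDelayRange(), c(0.06, 0.25))
})

test_that("uncoupled deterministic node converges to the algebraic fixed point", {
  p <- neuralMassParams(noiseAmplitude = 0)
  # independent oracle: scalar root of the composed equilibrium map
  g <- function(ye) {
    yi <- p@B / p@b * sigmoidI(p@Cie * ye, p)
    ye - p@A / p@a * sigmoidE(-p@Cei * yi, p)
  }
  yeStar <- uniroot(g, c(0, p@A * p@Fe / p@a), tol = 1e-14)$root
  conn <- handConnectome(3)
  sim <- simulateNetwork(conn, p, C = 0, tauGlobal = 0, duration = 2,
                         dt = 1e-3, seed = 1, transient = 3)
  finals <- sim$ye[, ncol(sim$ye)]
  expect_true(all(abs(finals - yeStar) < 1e-6))
  # package helper agrees with the root-finder
  expect_equal(nodeFixedPoint(p)$ye, yeStar, tolerance = 1e-9)
})

test_that("simulation is bit-identical given the seed and differs across seeds", {
  conn <- smallConnectome()
  a <- simulateNetwork(conn, C = 64, tauGlobal = 0.168, duration = 2,
                       dt = 2e-3, seed = 5, transient = 1)
  b <- simulateNetwork(conn, C = 64, tauGlobal = 0.168, duration = 2,
                       dt = 2e-3, seed = 5, transient = 1)
  d <- simulateNetwork(conn, C = 64, tauGlobal = 0.168, duration = 2,
                       dt = 2e-3, seed = 6, transient = 1)
  expect_identical(a$ye, b$ye)
  expect_false(identical(a$ye, d$ye))
})

test_that("deterministic dynamics are insensitive to halving the step", {
  conn <- smallConnectome()
  p0 <- neuralMassParams(noiseAmplitude = 0)
  s1 <- simulateNetwork(conn, p0, C = 70, tauGlobal = 0.168, duration = 20,
                        dt = 1e-3, seed = 1, transient = 10)
  s2 <- simulateNetwork(conn, p0, C = 70, tauGlobal = 0.168, duration = 20,
                        dt = 5e-4, seed = 1, transient = 10)
  m1 <- mean(s1$ye); m2 <- mean(s2$ye)
  expect_lt(abs(m1 - m2) / abs(m2), 0.02)
  v1 <- var(as.vector(s1$ye)); v2 <- var(as.vector(s2$ye))
  expect_lt(abs(v1 - v2) / max(v2, 1e-12), 0.02)
})

test_that("variance of the delayed coupling drive grows with C", {
  conn <- smallConnectome()
  cw <- couplingFromSC(conn)
  driveVar <- function(C) {
    sim <- simulateNetwork(conn, C = C, tauGlobal = 0, duration = 10,
                           dt = 2e-3, seed = 3, transient = 5)
    drive <- (C / nRegions(conn)) * cw$cnm %*% sim$ye
    mean(apply(drive, 1, var))
  }
  vs <- vapply(c(0, 10, 30), driveVar, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("overly coarse steps and bad inputs are rejected", {
  conn <- smallConnectome()
  expect_error(simulateNetwork(conn, dt = 0.01), "too large")
  expect_error(simulateNetwork(conn, dt = 0), "positive")
  expect_error(simulateNetwork(conn, C = -1), "non-negative")
})

test_that("Welch PSD locates tones and keeps Parseval consistency", {
  dt <- 0.01
  t <- seq(0, 60, dt)
  x <- sin(2 * pi * 5 * t)
  psd <- welchPSD(x, dt)
  expect_equal(psd$freq[which.max(psd$power)], 5, tolerance = 0.1)
  # two tones -> two local maxima at their bins
  y <- sin(2 * pi * 3 * t) + sin(2 * pi * 12 * t)
  psdY <- welchPSD(y, dt)
  top <- order(psdY$power, decreasing = TRUE)[1:4]
  peaks <- sort(unique(round(psdY$freq[top])))
  expect_true(all(c(3, 12) %in% peaks))
  # integral of the PSD approximates the variance
  df <- diff(psdY$freq[1:2])
  expect_equal(sum(psdY$power) * df, var(y), tolerance = 0.15)
  expect_error(welchPSD(x[1:10], dt), "64")
})

test_that("white-noise PSD is flat on log-log axes", {
  set.seed(42)
  slopes <- replicate(5, {
    x <- rnorm(8192)
    psd <- welchPSD(x, 0.01)
    keep <- psd$freq > 1          # away from the lowest bins
    coef(lm(log(psd$power[keep]) ~ log(psd$freq[keep])))[2]
  })
  expect_lt(abs(mean(slopes)), 0.05)
})
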