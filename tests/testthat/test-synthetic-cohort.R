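test_that("demography has the configured sizes and enumerations", {
  cfg <- syntheticConfig(nRegions = 6)
  co <- generateDemography(cfg, seed = 3)
  s <- subjectTable(co)
  expect_equal(nrow(s), 116)
  expect_equal(sum(s$group == "HC"), 51)
  expect_equal(sum(s$group == "PD"), 65)
  expect_true(all(s$sex %in% c("F", "M")))
  expect_true(all(s$age >= 18))
  expect_false(anyDuplicated(s$id) > 0)
  empty <- generateDemography(syntheticConfig(nHC = 0, nPD = 0, nRegions = 6))
  expect_equal(nrow(subjectTable(empty)), 0)
})

test_that("patient ages recover the configured moments over seeds", {
  cfg <- syntheticConfig(nRegions = 6)
  means <- vapply(1:100, function(s) {
    tab <- subjectTable(generateDemography(cfg, seed = s))
    mean(tab$age[tab$group == "PD"])
  }, numeric(1))
  se <- 9.62 / sqrt(65)
  expect_lt(abs(mean(means) - 62.0), 3 * se / sqrt(100) * 10)  # generous MC slack
  expect_lt(abs(mean(means) - 62.0), 3 * se)
})

test_that("generated connectomes satisfy the structural invariants exactly", {
  cfg <- syntheticConfig(nRegions = 12)
  for (s in 1:5) {
    conn <- generateConnectome(cfg, sprintf("sub%02d", s), seed = s)
    sc <- scMatrix(conn); pl <- plMatrix(conn)
    expect_identical(sc, t(sc))
    expect_identical(pl, t(pl))
    expect_equal(diag(sc), rep(0, 12))
    expect_true(all(sc >= 0) && all(sc == round(sc)))
    nz <- pl[sc > 0]
    expect_true(all(nz >= 2.5 & nz <= 250))       # tracking length limits
    expect_true(all(pl[sc == 0] == 0))
  }
  a <- generateConnectome(cfg, "same", seed = 9)
  b <- generateConnectome(cfg, "same", seed = 9)
  expect_identical(scMatrix(a), scMatrix(b))       # deterministic given seed
  expect_error(generateConnectome(syntheticConfig(nRegions = 6), "x", 1),
               NA)
  cfg1 <- syntheticConfig(nRegions = 6)
  cfg1@nRegions <- 1L
  expect_error(generateConnectome(cfg1, "x", 1), "nRegions")
})

test_that("empirical BOLD has the scan length and honours the noise switch", {
  cfg <- syntheticConfig(nRegions = 5, duration = 663, tr = 2.21, dt = 2e-3,
                         transient = 5, seed = 2)
  conn <- generateConnectome(cfg, "hc001")
  subj <- list(id = "hc001", group = "HC")
  ts <- generateEmpiricalBold(subj, conn, cfg)
  expect_equal(dim(tsValues(ts)), c(5, 300))       # 663 s at TR 2.21 s
  cfg0 <- cfg; cfg0@measurementNoiseSd <- 0
  a <- generateEmpiricalBold(subj, conn, cfg0)
  b <- generateEmpiricalBold(subj, conn, cfg0)
  expect_identical(tsValues(a), tsValues(b))       # noiseless = deterministic
  ts2 <- generateEmpiricalBold(subj, conn, cfg, seed = 99)
  expect_gt(mean(tsValues(ts) != tsValues(ts2)), 0.99)  # seeds change output
  bad <- list(id = "x", group = "PD")
  cfgNoGT <- cfg; cfgNoGT@groundTruth <- list(HC = c(C = 64, tau = 0.168))
  expect_error(generateEmpiricalBold(bad, conn, cfgNoGT), "ground truth")
})

test_that("balanced subset drops exactly the oldest patients", {
  co <- tinyCohort(4, 3)
  s <- subjectTable(co)
  s$age[s$group == "PD"] <- c(70, 60, 65)
  co <- makeCohort(s)
  out <- subjectTable(balancedSubset(co, 1))
  expect_equal(sort(out$age[out$group == "PD"]), c(60, 65))
  expect_equal(sum(out$group == "HC"), 4)          # controls untouched
  expect_identical(subjectTable(balancedSubset(co, 0)), subjectTable(co))
  expect_error(balancedSubset(co, 5), "exceeds")
  # study-scale case: 116 subjects minus the 17 oldest patients
  cfg <- syntheticConfig(nRegions = 6)
  big <- generateDemography(cfg, seed = 1)
  expect_equal(nrow(subjectTable(balancedSubset(big, 17))), 99)
})

test_that("stratified subsampling is sex-balanced and covers the cohort", {
  cfg <- syntheticConfig(nRegions = 6)
  co <- generateDemography(cfg, seed = 5)
  sub <- stratifiedSubsample(co, 36, seed = 1)
  s <- subjectTable(sub)
  expect_equal(nrow(s), 72)
  expect_equal(sum(s$group == "HC"), 36)
  expect_equal(sum(s$group == "PD"), 36)
  # male fraction close to the cohort per group
  full <- subjectTable(co)
  for (g in c("HC", "PD")) {
    pCohort <- mean(full$sex[full$group == g] == "M")
    pSub <- mean(s$sex[s$group == g] == "M")
    expect_lt(abs(pSub - pCohort), 0.06)
  }
  # exhaustive case returns the whole group
  nHC <- sum(full$group == "HC")
  expect_error(stratifiedSubsample(co, nHC + 1), "fewer")
  # coverage: union over 100 seeds includes nearly everyone
  seen <- unique(unlist(lapply(1:100, function(k)
    subjectTable(stratifiedSubsample(co, 36, seed = k))$id)))
  expect_gt(length(seen) / nrow(full), 0.95)
})

test_that("cohort and config objects validate their invariants", {
  expect_error(makeCohort(data.frame(id = c("a", "a"), group = "HC",
                                     sex = "F", age = 50)), "unique")
  expect_error(makeCohort(data.frame(id = "a", group = "XX",
                                     sex = "F", age = 50)), "HC or PD")
  expect_error(syntheticConfig(tr = 700), "tr < duration")
  expect_error(syntheticConfig(plBounds = c(5, 2)), "increasing")
})
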