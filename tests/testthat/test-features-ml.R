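# landscape stacks with named subjects for feature assembly
featureFixture <- function(n = 20, seed = 1, planted = 0) {
  ids <- sprintf("s%03d", seq_len(n))
  labels <- rep(c("HC", "PD"), length.out = n)
  set.seed(seed)
  mk <- function(shift) {
    ls <- lapply(labels, function(g) {
      m <- matrix(rnorm(16 * 11, 0, 0.05), 16, 11)
      if (g == "PD") m[5:7, 4:6] <- m[5:7, 4:6] + shift
      m
    })
    names(ls) <- ids
    ls
  }
  atlasData <- list(
    schaefer_like = list(eFC_sFC = mk(planted), eSC_sFC = mk(0),
                         empCorr = setNames(rnorm(n, 0.3, 0.05), ids)),
    desikan_like = list(eFC_sFC = mk(0), eSC_sFC = mk(0),
                        empCorr = setNames(rnorm(n, 0.25, 0.05), ids)))
  behOptima <- list(schaefer_like = list(eFC_sFC = c(6L, 5L), eSC_sFC = c(2L, 2L)),
                    desikan_like = list(eFC_sFC = c(3L, 3L), eSC_sFC = c(4L, 4L)))
  list(ids = ids, labels = labels, atlasData = atlasData,
       behOptima = behOptima, ages = 50 + seq_len(n))
}

test_that("feature assembly yields five named features per atlas", {
  fx <- featureFixture()
  X <- assembleFeatures(fx$ids, fx$atlasData, fx$behOptima)
  expect_equal(ncol(X), 10)
  expect_equal(nrow(X), 20)
  expect_true(all(grepl("^(schaefer|desikan)_like\\.(emp|nii|beh)_", colnames(X))))
  one <- assembleFeatures(fx$ids, fx$atlasData["schaefer_like"],
                          fx$behOptima["schaefer_like"])
  expect_equal(ncol(one), 5)
  # nii features are the per-subject landscape maxima
  expect_equal(unname(X[, "schaefer_like.nii_eFC_sFC"]),
               vapply(fx$atlasData$schaefer_like$eFC_sFC, max, numeric(1),
                      USE.NAMES = FALSE))
  # beh features are the landscape values at the behavioural optimum
  expect_equal(unname(X[3, "desikan_like.beh_eFC_sFC"]),
               fx$atlasData$desikan_like$eFC_sFC[[3]][3, 3])
  expect_error(assembleFeatures(fx$ids, fx$atlasData,
                                list(schaefer_like = list())), "optimum")
})

test_that("shuffling preserves multisets and destroys correspondence", {
  fx <- featureFixture()
  X <- assembleFeatures(fx$ids, fx$atlasData, fx$behOptima)
  expect_identical(shuffleFeatures(X, character(0)), X)
  cn <- "schaefer_like.emp_eFC_eSC"
  Y <- shuffleFeatures(X, cn, seed = 3)
  expect_equal(sort(unname(Y[, cn])), sort(unname(X[, cn])))
  expect_false(all(Y[, cn] == X[, cn]))
  other <- setdiff(colnames(X), cn)
  expect_identical(Y[, other], X[, other])
  expect_error(shuffleFeatures(X, "nope"), "unknown column")
  # permutation-null: shuffled column decorrelates from the original
  set.seed(1)
  n <- 116
  v <- rnorm(n)
  M <- cbind(a = v)
  rs <- vapply(1:100, function(k)
    abs(cor(shuffleFeatures(M, "a", seed = k)[, "a"], v)), numeric(1))
  expect_lt(mean(rs), 0.1)
})

test_that("condition tags select the right columns to shuffle", {
  cn <- c("schaefer_like.emp_eFC_eSC", "schaefer_like.nii_eFC_sFC",
          "schaefer_like.beh_eSC_sFC", "desikan_like.emp_eFC_eSC")
  expect_setequal(conditionShuffleColumns("all", cn), character(0))
  expect_setequal(conditionShuffleColumns("empirical_only", cn), cn[2:3])
  expect_setequal(conditionShuffleColumns("simulated_only", cn), cn[c(1, 4)])
  expect_setequal(conditionShuffleColumns("nii_only", cn), cn[c(1, 3, 4)])
})

test_that("confound regression matches closed-form OLS and never leaks", {
  ages <- c(40, 50, 60, 70, 80)
  f1 <- 2 * ages + 3                                   # perfect confound
  f2 <- c(1, -2, 0, 2, -1)                             # age-independent
  X <- cbind(f1 = f1, f2 = f2)
  cf <- fitConfound(X, ages)
  res <- applyConfound(X, ages, cf)
  expect_equal(unname(res[, "f1"]), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(res[, "f2"]), f2 - mean(f2), tolerance = 1e-10)
  # held-out subject residualised with training coefficients (hand OLS)
  b <- coef(lm(f1 ~ ages))
  newAge <- 95; newVal <- 100
  out <- applyConfound(matrix(c(newVal, 0), 1,
                              dimnames = list(NULL, c("f1", "f2"))),
                       newAge, cf)
  expect_equal(out[1, "f1"], newVal - (b[1] + b[2] * newAge),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(fitConfound(X, rep(50, 5)), "constant")
})

test_that("LASSO training honours the penalty limits and is deterministic", {
  set.seed(2)
  n <- 60
  x <- cbind(sig = c(runif(n / 2, -3, -1), runif(n / 2, 1, 3)),
             noise = rnorm(n))
  y <- rep(c("HC", "PD"), each = n / 2)
  # huge penalty -> intercept-only model predicting the prevalence
  m0 <- lassoLogisticTrain(x, y, lambdaGrid = c(1e5, 9e4, 8e4), seed = 1)
  expect_equal(unname(m0$weights), c(0, 0))
  expect_equal(predictProba(m0, x)[1], mean(y == "PD"), tolerance = 1e-6)
  # separated feature at small penalty classifies the training set
  m1 <- lassoLogisticTrain(x, y, lambdaGrid = c(0.02, 0.01, 0.005, 0.002),
                           seed = 1)
  pred <- predictProba(m1, x) >= 0.5
  expect_equal(mean(pred == (y == "PD")), 1)
  m2 <- lassoLogisticTrain(x, y, lambdaGrid = c(0.02, 0.01, 0.005, 0.002),
                           seed = 1)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$weights, m2$weights)
  m3 <- lassoLogisticTrain(x, y, seed = 1)   # auto-scaled path, same seed
  expect_identical(m3$lambda, lassoLogisticTrain(x, y, seed = 1)$lambda)
  expect_error(lassoLogisticTrain(x, rep("PD", n)), "single class")
})

test_that("predicted probabilities follow the logistic form", {
  model <- structure(list(intercept = 0.5,
                          weights = c(a = 2, b = -1),
                          lambda = 0.1, featureNames = c("a", "b")),
                     class = "dynconnLasso")
  X <- matrix(c(1, 0.5, -1, 2), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predictProba(model, X),
               plogis(0.5 + X %*% c(2, -1))[, 1], ignore_attr = TRUE)
  zero <- structure(list(intercept = 0, weights = c(a = 0, b = 0),
                         featureNames = c("a", "b")), class = "dynconnLasso")
  expect_equal(predictProba(zero, X), c(0.5, 0.5))
  expect_gt(predictProba(model, matrix(c(100, 0), 1,
            dimnames = list(NULL, c("a", "b"))))[1], 0.999)
  expect_error(predictProba(model, matrix(0, 1, 2)), "columns")
})

test_that("nested CV produces the full prediction record structure", {
  fx <- featureFixture(n = 40, planted = 0.3)
  provider <- landscapeFeatureProvider(fx$ids, fx$labels, fx$atlasData,
                                      grid = deskGrid())
  rec <- nestedCV(fx$labels, fx$ages, provider, condition = "all",
                  repeats = 2, seed = 3, subjectIds = fx$ids)
  expect_equal(nrow(rec), 40 * 2)                # every subject once per repeat
  expect_equal(length(unique(rec$fold)), 5)
  expect_true(all(rec$probability >= 0 & rec$probability <= 1))
  expect_true(all(table(rec$subject) == 2))
  # determinism
  rec2 <- nestedCV(fx$labels, fx$ages, provider, condition = "all",
                   repeats = 2, seed = 3, subjectIds = fx$ids)
  expect_identical(rec$probability, rec2$probability)
})

test_that("pure-noise features stay near chance under the full pipeline", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 6), n,
              dimnames = list(NULL, paste0("a.emp_f", 1:6)))
  labels <- rep(c("HC", "PD"), each = n / 2)
  ages <- rnorm(n, 60, 8)
  rec <- nestedCV(labels, ages, cachedFeatureProvider(X), condition = "all",
                  repeats = 5, seed = 6)
  perFold <- split(rec, list(rec$repeatIndex, rec$fold))
  bal <- vapply(perFold, function(r)
    confusionMetrics(r)$balancedAccuracy, numeric(1))
  expect_gt(median(bal, na.rm = TRUE), 0.25)
  expect_lt(median(bal, na.rm = TRUE), 0.75)
})

test_that("confusion metrics match their definitions", {
  rec <- data.frame(probability = c(0.9, 0.8, 0.6, 0.4, 0.2, 0.7, 0.3, 0.1),
                    label = c(1, 1, 1, 1, 1, 0, 0, 0))
  cm <- confusionMetrics(rec)
  expect_equal(cm$TP, 3); expect_equal(cm$FN, 2)
  expect_equal(cm$TN, 2); expect_equal(cm$FP, 1)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 2 / 3)
  expect_equal(cm$balancedAccuracy, (0.6 + 2 / 3) / 2)
  # ties at the threshold are classified positive
  tie <- data.frame(probability = rep(0.5, 4), label = c(1, 1, 0, 0))
  cmT <- confusionMetrics(tie, threshold = 0.5)
  expect_equal(cmT$TP, 2); expect_equal(cmT$FP, 2)
  expect_equal(cmT$TN, 0); expect_equal(cmT$FN, 0)
  perfect <- data.frame(probability = c(0.9, 0.1), label = c(1, 0))
  expect_equal(confusionMetrics(perfect)$accuracy, 1)
  expect_equal(confusionMetrics(perfect)$balancedAccuracy, 1)
  expect_error(confusionMetrics(rec[0, ]), "no records")
})

test_that("AUC equals the Mann-Whitney statistic and behaves at the ends", {
  perfect <- data.frame(probability = c(0.9, 0.8, 0.2, 0.1),
                        label = c(1, 1, 0, 0))
  expect_equal(rocAuc(perfect)$auc, 1)
  set.seed(12)
  for (k in 1:5) {
    n <- 50
    rec <- data.frame(probability = round(runif(n), 2),   # force ties
                      label = rbinom(n, 1, 0.5))
    if (length(unique(rec$label)) < 2) next
    auc <- rocAuc(rec)$auc
    pos <- rec$probability[rec$label == 1]
    neg <- rec$probability[rec$label == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
    ref <- suppressMessages(pROC::auc(rec$label, rec$probability,
                                      direction = "<"))
    expect_equal(auc, as.numeric(ref), tolerance = 1e-12)
  }
  expect_error(rocAuc(data.frame(probability = 0.5, label = 1)), "both classes")
})

test_that("leakage guards reject malformed providers", {
  fx <- featureFixture(n = 20)
  badProvider <- function(trainIdx) matrix(0, 5, 2,
                                           dimnames = list(NULL, c("a.emp_x", "b.emp_y")))
  expect_error(nestedCV(fx$labels, fx$ages, badProvider, repeats = 1, seed = 1),
               "all subjects")
})
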