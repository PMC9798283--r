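#' Assemble the connectome-relationship feature table
#'
#' Builds the per-subject feature matrix used for classification: for each
#' parcellation, five features — the empirical structure-function
#' relationship corr(eFC, eSC); corr(eFC, sFC) and corr(eSC, sFC) at each
#' subject's own neuroimaging optimum (the landscape maximum); and
#' corr(eFC, sFC) and corr(eSC, sFC) at the group-level behavioural optimum.
#' Column names are \code{<atlas>.<emp_eFC_eSC|nii_eFC_sFC|nii_eSC_sFC|}
#' \code{beh_eFC_sFC|beh_eSC_sFC>}.
#'
#' @param subjectIds character vector defining row order.
#' @param atlasData named list (one entry per atlas), each a list with
#'   \code{eFC_sFC} and \code{eSC_sFC} (named lists, per subject id, of
#'   landscape matrices or \linkS4class{GoFLandscape} objects) and
#'   \code{empCorr} (named numeric of corr(eFC, eSC) per subject).
#' @param behOptima named list per atlas, each a list with \code{eFC_sFC} and
#'   \code{eSC_sFC} entries giving the behavioural-optimum grid indices
#'   c(couplingIndex, delayIndex).
#' @return numeric matrix, subjects x (5 per atlas), with row and column
#'   names.
#' @export
assembleFeatures <- function(subjectIds, atlasData, behOptima) {
  .landMat <- function(l) if (is(l, "GoFLandscape")) l@values else l
  cols <- list()
  for (atlas in names(atlasData)) {
    ad <- atlasData[[atlas]]
    bo <- behOptima[[atlas]]
    if (is.null(bo$eFC_sFC) || is.null(bo$eSC_sFC))
      stop(sprintf("missing behavioural optimum for atlas %s", atlas))
    getCol <- function(fun) vapply(subjectIds, fun, numeric(1))
    need <- function(lst, id) {
      if (is.null(lst[[id]]))
        stop(sprintf("missing landscape for subject %s, atlas %s", id, atlas))
      .landMat(lst[[id]])
    }
    cols[[paste0(atlas, ".emp_eFC_eSC")]] <- getCol(function(id) {
      v <- ad$empCorr[[id]]
      if (is.null(v)) stop(sprintf("missing empirical corr for %s/%s", id, atlas))
      v
    })
    cols[[paste0(atlas, ".nii_eFC_sFC")]] <- getCol(function(id)
      max(need(ad$eFC_sFC, id)))
    cols[[paste0(atlas, ".nii_eSC_sFC")]] <- getCol(function(id)
      max(need(ad$eSC_sFC, id)))
    cols[[paste0(atlas, ".beh_eFC_sFC")]] <- getCol(function(id)
      need(ad$eFC_sFC, id)[bo$eFC_sFC[1], bo$eFC_sFC[2]])
    cols[[paste0(atlas, ".beh_eSC_sFC")]] <- getCol(function(id)
      need(ad$eSC_sFC, id)[bo$eSC_sFC[1], bo$eSC_sFC[2]])
  }
  out <- do.call(cbind, cols)
  rownames(out) <- subjectIds
  out
}

#' Feature-shuffling conditions
#'
#' Maps a condition tag to the feature columns whose subject correspondence
#' is destroyed by shuffling: \code{empirical_only} shuffles the simulated
#' (nii_*/beh_*) features, \code{simulated_only} shuffles the empirical
#' (emp_*) features, \code{all} shuffles nothing, \code{nii_only} keeps only
#' the neuroimaging-fit features intact and \code{beh_only} only the
#' behavioural-fit features.
#'
#' @param condition condition tag.
#' @param columnNames feature column names.
#' @return character vector of columns to shuffle.
#' @export
conditionShuffleColumns <- function(condition, columnNames) {
  condition <- match.arg(condition, c("empirical_only", "simulated_only",
                                      "all", "nii_only", "beh_only"))
  kind <- sub("^[^.]*\\.", "", columnNames)
  kind <- sub("_.*$", "", kind)
  keep <- switch(condition,
                 empirical_only = "emp",
                 simulated_only = c("nii", "beh"),
                 all = c("emp", "nii", "beh"),
                 nii_only = "nii",
                 beh_only = "beh")
  columnNames[!(kind %in% keep)]
}

#' Shuffle feature columns across subjects
#'
#' Independently permutes each selected column across subjects, preserving
#' each column's multiset of values while destroying its correspondence to
#' individual subjects.  Unselected columns are untouched.
#'
#' @param features numeric matrix with column names.
#' @param columns character vector of columns to shuffle (may be empty).
#' @param seed integer seed.
#' @return the matrix with selected columns permuted.
#' @export
shuffleFeatures <- function(features, columns, seed = 1) {
  if (!length(columns)) return(features)
  unknown <- setdiff(columns, colnames(features))
  if (length(unknown))
    stop(sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
  set.seed(.subSeed(seed, "shuffle"))
  for (cn in columns)
    features[, cn] <- features[sample.int(nrow(features)), cn]
  features
}

#' Cross-validated confound (age) regression
#'
#' \code{fitConfound} fits, per feature, an ordinary least-squares regression
#' of the feature on (1, age) using training subjects only.
#' \code{applyConfound} subtracts the training-fitted line from any subjects'
#' features (training residuals, or out-of-sample residualisation of test
#' subjects with the training coefficients).
#'
#' @param features numeric matrix (subjects x features).
#' @param ages numeric vector of ages aligned with rows.
#' @return \code{fitConfound}: 2 x P matrix of (intercept, slope) per
#'   feature; \code{applyConfound}: residualised feature matrix.
#' @export
fitConfound <- function(features, ages) {
  if (length(unique(ages)) < 2) stop("age is constant in the training set")
  x <- cbind(1, ages)
  coef <- solve(crossprod(x), crossprod(x, features))
  rownames(coef) <- c("intercept", "age")
  coef
}

#' @rdname fitConfound
#' @param coefficients output of \code{fitConfound}.
#' @export
applyConfound <- function(features, ages, coefficients) {
  features - cbind(1, ages) %*% coefficients
}

#' L1-penalised logistic regression with inner cross-validation
#'
#' Fits the logistic LASSO along a lambda path (50 log-spaced values
#' auto-scaled from the data by default) and selects the penalty minimising
#' the mean 10-fold cross-validated binomial deviance; the returned model is
#' the path fit on the full training set at the selected lambda.  Patients
#' (PD) are the positive class.
#'
#' @param X training feature matrix.
#' @param y labels (\code{"HC"}/\code{"PD"} or 0/1 with 1 = patient).
#' @param lambdaGrid optional explicit lambda path.
#' @param nLambda path length when auto-scaled (default 50).
#' @param innerFolds folds of the inner CV (default 10).
#' @param seed integer seed (fold assignment).
#' @return object of class \code{dynconnLasso}: weights, intercept, lambda,
#'   feature names, and the underlying cv.glmnet fit.
#' @export
lassoLogisticTrain <- function(X, y, lambdaGrid = NULL, nLambda = 50,
                               innerFolds = 10, seed = 1) {
  y01 <- .binaryLabels(y)
  if (length(unique(y01)) < 2) stop("training set has a single class")
  if (min(table(y01)) < 2) stop("need at least 2 subjects per class")
  X <- as.matrix(X)
  set.seed(.subSeed(seed, "foldid"))
  foldid <- integer(length(y01))
  for (cls in c(0, 1)) {
    idx <- which(y01 == cls)
    foldid[idx] <- sample(rep_len(seq_len(innerFolds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(X, y01, family = "binomial",
                          lambda = lambdaGrid, nlambda = nLambda,
                          foldid = foldid, type.measure = "deviance",
                          standardize = TRUE)
  lam <- cv$lambda.min
  co <- as.numeric(stats::coef(cv, s = lam))
  structure(list(intercept = co[1],
                 weights = setNames(co[-1], colnames(X)),
                 lambda = lam, featureNames = colnames(X), cvFit = cv),
            class = "dynconnLasso")
}

.binaryLabels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% .GROUPS)) stop("labels must be HC/PD or 0/1")
  as.numeric(y == "PD")
}

#' Predicted probabilities from a trained classifier
#'
#' Logistic transform of the linear score; probabilities are the predicted
#' chance of being a patient.
#'
#' @param model a \code{dynconnLasso} object.
#' @param X feature matrix with the training columns.
#' @return probabilities in (0, 1).
#' @export
predictProba <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model$featureNames))
    stop("feature columns do not match the training columns")
  as.numeric(plogis(model$intercept + X %*% model$weights))
}

#' Cached-feature provider for nested CV
#'
#' Wraps a fixed feature matrix as a feature provider (used when features do
#' not depend on the training split).
#'
#' @param features subjects x features matrix.
#' @return provider function(trainIdx) -> features for all subjects.
#' @export
cachedFeatureProvider <- function(features) {
  force(features)
  function(trainIdx) features
}

#' Landscape-based feature provider with cross-validated behavioural fitting
#'
#' Returns a provider that, given the training subject indices of an outer
#' fold, re-runs the behavioural model fitting on the training subjects only
#' (per atlas and relationship), falls back to the training-set maximal
#' absolute effect size when the significance mask is empty, and assembles
#' features for all subjects at those training-derived optima.  Test subjects
#' never enter the behavioural fit (asserted).
#'
#' @param subjectIds all subject ids (row order).
#' @param labels group labels aligned with \code{subjectIds}.
#' @param atlasData see \code{\link{assembleFeatures}}.
#' @param alpha,fwhm behavioural-fitting settings.
#' @param grid the \linkS4class{ParameterGrid} shared by the landscapes
#'   (taken from them when they are \linkS4class{GoFLandscape} objects).
#' @return provider function(trainIdx) -> feature matrix for all subjects.
#' @export
landscapeFeatureProvider <- function(subjectIds, labels, atlasData,
                                     alpha = 0.05, fwhm = 3, grid = NULL) {
  force(subjectIds); force(labels); force(atlasData); force(grid)
  function(trainIdx) {
    stopifnot(all(trainIdx %in% seq_along(subjectIds)))
    trainIds <- subjectIds[trainIdx]
    behOptima <- lapply(atlasData, function(ad) {
      lapply(list(eFC_sFC = ad$eFC_sFC, eSC_sFC = ad$eSC_sFC), function(ls) {
        used <- ls[trainIds]
        stopifnot(identical(names(used), trainIds))  # leakage guard
        fit <- behaviouralFit(used, labels[trainIdx], alpha = alpha,
                              fwhm = fwhm, grid = grid)
        if (length(fit@optimum) == 2L) fit@optimum else {
          es <- fit@effectSize
          as.integer(which(abs(es) == max(abs(es)), arr.ind = TRUE)[1, ])
        }
      })
    })
    assembleFeatures(subjectIds, atlasData, behOptima)
  }
}

#' Nested cross-validation for patient classification
#'
#' The full leakage-safe protocol: per repeat, subjects are randomly split
#' into \code{outerFolds} stratified subsets; for each outer fold the feature
#' provider recomputes any training-dependent quantities (behavioural optima)
#' on the training subjects only; the condition's shuffling is applied with a
#' repeat-derived sub-seed; the confound (age) regression is fitted on the
#' training set and applied to training and test subjects; the logistic LASSO
#' is trained with inner \code{innerFolds}-fold CV; and the held-out
#' subjects' predicted probabilities are recorded.
#'
#' @param labels group labels (HC/PD) for all subjects, in cohort order.
#' @param ages ages aligned with \code{labels}.
#' @param featureProvider function(trainIdx) -> subjects x features matrix.
#' @param condition shuffling condition tag (see
#'   \code{\link{conditionShuffleColumns}}).
#' @param outerFolds,innerFolds,repeats protocol sizes (defaults 5, 10, 50).
#' @param seed master seed.
#' @param subjectIds optional ids stored in the records.
#' @return data.frame of prediction records: subject, repeat index, outer
#'   fold, predicted probability, true label (1 = PD), condition.
#' @export
nestedCV <- function(labels, ages, featureProvider, condition = "all",
                     outerFolds = 5, innerFolds = 10, repeats = 50,
                     seed = 1, subjectIds = NULL) {
  y01 <- .binaryLabels(labels)
  n <- length(y01)
  if (is.null(subjectIds)) subjectIds <- sprintf("s%03d", seq_len(n))
  records <- vector("list", repeats * outerFolds)
  k <- 0
  for (rep in seq_len(repeats)) {
    set.seed(.subSeed(seed, "split", rep))
    fold <- integer(n)
    for (cls in c(0, 1)) {
      idx <- which(y01 == cls)
      fold[idx] <- sample(rep_len(seq_len(outerFolds), length(idx)))
    }
    for (f in seq_len(outerFolds)) {
      testIdx <- which(fold == f)
      trainIdx <- which(fold != f)
      stopifnot(length(intersect(trainIdx, testIdx)) == 0,
                length(union(trainIdx, testIdx)) == n)  # leakage guard
      feats <- featureProvider(trainIdx)
      if (nrow(feats) != n) stop("provider must return features for all subjects")
      shuf <- conditionShuffleColumns(condition, colnames(feats))
      feats <- shuffleFeatures(feats, shuf, seed = .subSeed(seed, "shufrep", rep))
      conf <- fitConfound(feats[trainIdx, , drop = FALSE], ages[trainIdx])
      featsAdj <- applyConfound(feats, ages, conf)
      model <- lassoLogisticTrain(featsAdj[trainIdx, , drop = FALSE],
                                  y01[trainIdx], innerFolds = innerFolds,
                                  seed = .subSeed(seed, "lasso", rep, f))
      prob <- predictProba(model, featsAdj[testIdx, , drop = FALSE])
      k <- k + 1
      records[[k]] <- data.frame(subject = subjectIds[testIdx],
                                 repeatIndex = rep, fold = f,
                                 probability = prob, label = y01[testIdx],
                                 condition = condition,
                                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, records)
}

#' Confusion matrix and threshold metrics
#'
#' Thresholds predicted probabilities (ties at the threshold classified
#' positive) and reports the confusion counts with accuracy, sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and balanced accuracy (their mean).
#'
#' @param records data.frame with \code{probability} and \code{label}
#'   (1 = patient/positive).
#' @param threshold classification threshold (default 0.5).
#' @return list with TP, FP, TN, FN, accuracy, sensitivity, specificity,
#'   balancedAccuracy.
#' @export
confusionMetrics <- function(records, threshold = 0.5) {
  if (!nrow(records)) stop("no records")
  pred <- as.numeric(records$probability >= threshold)
  y <- records$label
  TP <- sum(pred == 1 & y == 1); FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0); FN <- sum(pred == 0 & y == 1)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / nrow(records),
       sensitivity = sens, specificity = spec,
       balancedAccuracy = mean(c(sens, spec)))
}

#' ROC curve and AUC
#'
#' Builds the ROC by sweeping the classification threshold over the predicted
#' probabilities and integrates the area under the curve by the trapezoidal
#' rule (equivalently, the probability that a random patient outranks a
#' random control, with ties counted half).
#'
#' @param records data.frame with \code{probability} and \code{label}.
#' @return list with \code{fpr}, \code{tpr} (threshold sweep) and \code{auc}.
#' @export
rocAuc <- function(records) {
  y <- records$label
  p <- records$probability
  if (length(unique(y)) < 2) stop("need both classes for a ROC curve")
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]; p <- p[ord]
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  distinct <- c(which(diff(p) != 0), length(p))
  tp <- cumsum(y == 1)[distinct]
  fp <- cumsum(y == 0)[distinct]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}
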