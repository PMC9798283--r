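#' Probability calibration curve
#'
#' Bins predicted probabilities into equal-width bins on [0, 1] and reports
#' the fraction of actual positives per bin; a well-calibrated classifier
#' aligns with the diagonal.
#'
#' @param records data.frame with \code{probability} and \code{label}.
#' @param nBins number of bins (>= 2, default 10).
#' @return data.frame with binCenter, fractionPositive (NA for empty bins),
#'   count.
#' @export
calibrationCurve <- function(records, nBins = 10) {
  if (!nrow(records)) stop("no records")
  if (nBins < 2) stop("need at least 2 bins")
  p <- records$probability
  bin <- pmin(floor(p * nBins) + 1L, nBins)
  centers <- (seq_len(nBins) - 0.5) / nBins
  frac <- rep(NA_real_, nBins)
  cnt <- integer(nBins)
  for (b in seq_len(nBins)) {
    inb <- bin == b
    cnt[b] <- sum(inb)
    if (cnt[b]) frac[b] <- mean(records$label[inb])
  }
  data.frame(binCenter = centers, fractionPositive = frac, count = cnt)
}

#' Brier score
#'
#' Mean squared error of the predicted probabilities against the 0/1 labels.
#'
#' @param records data.frame with \code{probability} and \code{label}.
#' @return score in [0, 1]; 0 is perfect, 0.25 is constant 0.5.
#' @export
brierScore <- function(records) {
  if (!nrow(records)) stop("no records")
  mean((records$probability - records$label)^2)
}

#' Wasserstein distance to the uniform distribution
#'
#' Exact 1-Wasserstein distance between the empirical distribution of the
#' predicted probabilities and the uniform distribution on [0, 1], computed
#' as the integral of |empirical CDF - x| (no binning).  Lower values mean
#' the probabilities are spread more uniformly.
#'
#' @param probabilities values in [0, 1].
#' @return distance in [0, 0.5].
#' @export
wassersteinToUniform <- function(probabilities) {
  if (!length(probabilities)) stop("empty input")
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  x <- sort(probabilities)
  n <- length(x)
  knots <- c(0, x, 1)
  total <- 0
  for (i in seq_len(n + 1)) {
    a <- knots[i]; b <- knots[i + 1]
    if (b <= a) next
    cdf <- (i - 1) / n
    # integral of |cdf - x| over [a, b]
    if (cdf <= a) total <- total + ((a - cdf) + (b - cdf)) * (b - a) / 2
    else if (cdf >= b) total <- total + ((cdf - a) + (cdf - b)) * (b - a) / 2
    else total <- total + ((cdf - a)^2 + (b - cdf)^2) / 2
  }
  total
}

#' Per-fold performance summary and condition comparisons
#'
#' Computes, per condition, the per-(repeat, fold) test metrics (accuracy,
#' sensitivity, specificity, balanced accuracy, AUC), their medians and
#' interquartile ranges over all outer-fold tests, and pairwise paired
#' Wilcoxon signed-rank comparisons of balanced accuracy across conditions on
#' matched (repeat, fold) tests, Bonferroni-corrected, with Rosenthal effect
#' sizes.
#'
#' @param recordsList named list of prediction-record data.frames (one per
#'   condition), with matched repeat/fold structure.
#' @param threshold classification threshold for the confusion metrics.
#' @return list with \code{perTest} (long data.frame), \code{summary}
#'   (medians and IQRs) and \code{comparisons} (pairwise tests).
#' @export
summarizeConditions <- function(recordsList, threshold = 0.5) {
  if (length(recordsList) < 1) stop("no conditions")
  perTest <- list()
  for (cond in names(recordsList)) {
    rec <- recordsList[[cond]]
    sp <- split(rec, list(rec$repeatIndex, rec$fold), drop = TRUE)
    rows <- lapply(sp, function(r) {
      cm <- confusionMetrics(r, threshold)
      auc <- if (length(unique(r$label)) == 2) rocAuc(r)$auc else NA_real_
      data.frame(condition = cond, repeatIndex = r$repeatIndex[1],
                 fold = r$fold[1], accuracy = cm$accuracy,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 balancedAccuracy = cm$balancedAccuracy, auc = auc)
    })
    perTest[[cond]] <- do.call(rbind, rows)
  }
  perTest <- do.call(rbind, perTest)
  rownames(perTest) <- NULL
  metrics <- c("accuracy", "sensitivity", "specificity", "balancedAccuracy",
               "auc")
  summary <- do.call(rbind, lapply(split(perTest, perTest$condition),
    function(d) {
      out <- data.frame(condition = d$condition[1], nTests = nrow(d))
      for (m in metrics) {
        q <- quantile(d[[m]], c(0.25, 0.5, 0.75), na.rm = TRUE)
        out[[paste0(m, "Median")]] <- q[2]
        out[[paste0(m, "IQRlow")]] <- q[1]
        out[[paste0(m, "IQRhigh")]] <- q[3]
      }
      out
    }))
  rownames(summary) <- NULL
  comparisons <- NULL
  conds <- names(recordsList)
  if (length(conds) >= 2) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      a <- perTest[perTest$condition == pr[1], ]
      b <- perTest[perTest$condition == pr[2], ]
      key <- function(d) paste(d$repeatIndex, d$fold)
      if (!identical(sort(key(a)), sort(key(b))))
        stop("unmatched fold structures between conditions")
      a <- a[order(a$repeatIndex, a$fold), ]
      b <- b[order(b$repeatIndex, b$fold), ]
      d <- a$balancedAccuracy - b$balancedAccuracy
      if (all(d == 0)) {
        z <- 0; p <- 1; n <- length(d)
      } else {
        t <- signedRankTest(a$balancedAccuracy, b$balancedAccuracy)
        z <- t$z; p <- t$p; n <- t$n
      }
      data.frame(conditionA = pr[1], conditionB = pr[2], z = z, p = p,
                 effectSize = rosenthalEffectSize(z, max(n, 1)))
    })
    comparisons <- do.call(rbind, rows)
    comparisons$pBonferroni <- bonferroniAdjust(comparisons$p)
  }
  list(perTest = perTest, summary = summary, comparisons = comparisons)
}
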