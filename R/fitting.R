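#' Parameter grid constructor
#'
#' @param cValues strictly increasing global couplings.
#' @param tauValues strictly increasing global delays (s/m).
#' @return a \linkS4class{ParameterGrid}.
#' @export
parameterGrid <- function(cValues, tauValues) {
  new("ParameterGrid", cValues = as.numeric(cValues),
      tauValues = as.numeric(tauValues))
}

#' Default model-validation grid
#'
#' The full-scale grid has 64 couplings in [0, 120] and 43 delays in
#' [0, 0.42] s/m.  The coupling range densely covers the model's whole
#' dynamical repertoire — from the quiescent low-activity state through the
#' noise-and-delay-shaped oscillatory window (roughly C in [55, 90] for
#' typical connectomes, where the simulated FC is informative) up to
#' saturation — and the delay range keeps the biologically feasible band
#' (0.06 to 0.25 s/m) in the interior.  \code{deskGrid} is a coarse 16 x 11
#' version of the same ranges for desk-scale runs.
#'
#' @return a \linkS4class{ParameterGrid}.
#' @export
defaultGrid <- function() {
  parameterGrid(seq(0, 120, length.out = 64), seq(0, 0.42, length.out = 43))
}

#' @rdname defaultGrid
#' @export
deskGrid <- function() {
  parameterGrid(seq(0, 120, length.out = 16), seq(0, 0.42, length.out = 11))
}

#' Simulate a functional connectome at one grid point
#'
#' Forward model at (C, tauGlobal): network simulation, Balloon-Windkessel
#' conversion, band-pass filtering with the same band as applied to the
#' empirical BOLD, then Pearson FC.
#'
#' @param connectome a \linkS4class{StructuralConnectome}.
#' @param C global coupling.
#' @param tauGlobal global delay, s/m.
#' @param band frequency band applied to the simulated BOLD.
#' @param duration post-transient simulated time, s.
#' @param tr repetition time, s.
#' @param dt integration step, s.
#' @param seed integer seed.
#' @param nmParams,bwPar model parameter objects.
#' @param transient discarded initial time, s.
#' @param gain,bwDt hemodynamic drive gain and integration step (see
#'   \code{\link{simulateBold}}).
#' @return a simulated \linkS4class{FunctionalConnectome}.
#' @export
simulateSFC <- function(connectome, C, tauGlobal, band = "NF",
                        duration = 200, tr = 2.21, dt = 1e-3, seed = 1,
                        nmParams = neuralMassParams(), bwPar = bwParams(),
                        transient = 20, gain = 0.05, bwDt = 0.025) {
  ts <- simulateBold(connectome, C = C, tauGlobal = tauGlobal,
                     duration = duration, tr = tr, dt = dt, seed = seed,
                     nmParams = nmParams, bwPar = bwPar,
                     transient = transient, gain = gain, bwDt = bwDt)
  ts <- bandpassFilter(ts, band)
  pearsonFC(ts, source = "simulated")
}

#' Goodness-of-fit landscape for one subject
#'
#' For every grid point, simulates the subject's FC and computes the Pearson
#' correlation between the strict upper triangles of the empirical matrix
#' (eFC for relationship \code{"eFC-sFC"}, eSC for \code{"eSC-sFC"}) and the
#' simulated FC.  One stochastic realisation per grid point, with a
#' grid-point-derived sub-seed, so landscapes are reproducible.
#'
#' @param empirical the empirical matrix: a
#'   \linkS4class{FunctionalConnectome} or \linkS4class{StructuralConnectome}
#'   (or plain square matrix) to correlate against.
#' @param connectome the subject's \linkS4class{StructuralConnectome} (the
#'   simulation substrate).
#' @param grid a \linkS4class{ParameterGrid}.
#' @param relationship \code{"eFC-sFC"} or \code{"eSC-sFC"}.
#' @param band frequency band for the simulated BOLD.
#' @param subject subject identifier stored in the landscape.
#' @param atlas parcellation label stored in the landscape.
#' @param duration,tr,dt,transient forward-model settings (see
#'   \code{\link{simulateSFC}}).
#' @param seed master seed; each grid point uses a derived sub-seed.
#' @param nmParams,bwPar model parameter objects.
#' @param gain,bwDt hemodynamic drive gain and integration step (see
#'   \code{\link{simulateBold}}).
#' @return a \linkS4class{GoFLandscape}.
#' @export
gofLandscape <- function(empirical, connectome, grid,
                         relationship = c("eFC-sFC", "eSC-sFC"),
                         band = "NF", subject = "s1", atlas = "schaefer_like",
                         duration = 200, tr = 2.21, dt = 1e-3,
                         transient = 20, seed = 1,
                         nmParams = neuralMassParams(), bwPar = bwParams(),
                         gain = 0.05, bwDt = 0.025) {
  relationship <- match.arg(relationship)
  empMat <- .asSquareMatrix(empirical)
  nC <- length(grid@cValues); nTau <- length(grid@tauValues)
  values <- matrix(NA_real_, nC, nTau)
  failures <- character(0)
  for (j in seq_len(nTau)) {
    for (i in seq_len(nC)) {
      sfc <- tryCatch(
        simulateSFC(connectome, C = grid@cValues[i],
                    tauGlobal = grid@tauValues[j], band = band,
                    duration = duration, tr = tr, dt = dt,
                    seed = .subSeed(seed, "grid", subject, i, j),
                    nmParams = nmParams, bwPar = bwPar,
                    transient = transient, gain = gain, bwDt = bwDt),
        error = function(e) e)
      if (inherits(sfc, "error")) {
        failures <- c(failures, sprintf("(%d,%d): %s", i, j,
                                        conditionMessage(sfc)))
      } else {
        values[i, j] <- connectomeRelationship(empMat, sfc)
      }
    }
  }
  if (length(failures))
    stop(sprintf("landscape failed at %d grid point(s):\n%s",
                 length(failures), paste(head(failures, 5), collapse = "\n")))
  new("GoFLandscape", subject = subject, relationship = relationship,
      band = band, atlas = atlas, values = values, grid = grid)
}

#' Neuroimaging model fitting: landscape argmax
#'
#' Selects the grid point with the maximal GoF value.  Ties are broken
#' deterministically by the smallest delay, then the smallest coupling.
#'
#' @param landscape a \linkS4class{GoFLandscape} (or a plain matrix plus a
#'   \code{grid}).
#' @param grid required when \code{landscape} is a plain matrix.
#' @return list with \code{cOpt}, \code{tauOpt}, \code{gof} and the grid
#'   indices \code{index} = c(couplingIndex, delayIndex).
#' @export
neuroimagingFit <- function(landscape, grid = NULL) {
  if (is(landscape, "GoFLandscape")) {
    values <- landscape@values
    grid <- landscape@grid
  } else {
    values <- landscape
    if (is.null(grid)) stop("grid required for a plain matrix")
  }
  if (all(is.na(values))) stop("landscape is all-NA")
  mx <- max(values, na.rm = TRUE)
  hits <- which(values == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  idx <- hits[1, ]
  list(cOpt = grid@cValues[idx[1]], tauOpt = grid@tauValues[idx[2]],
       gof = mx, index = as.integer(idx))
}

# rank-sum z per column for two groups of rows stacked in a matrix; tie and
# continuity corrected, positive when group-1 values exceed group-2 values
.ranksumZColumns <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2); N <- n1 + n2
  both <- rbind(x1, x2)
  vapply(seq_len(ncol(both)), function(j) {
    ranksumZ(both[seq_len(n1), j], both[n1 + seq_len(n2), j])$z
  }, numeric(1))
}

#' Behavioural model fitting: group-difference map with RFT thresholding
#'
#' Per grid point, a two-tail Wilcoxon rank-sum test between the two groups'
#' GoF values gives a z map (sign convention: positive where controls exceed
#' patients) and a p map; the effect size is z divided by the square root of
#' the number of observations.  The z map is smoothed with a 2D Gaussian
#' kernel, standardised to unit null variance, and thresholded by the
#' random-field family-wise criterion at \code{alpha}.  The optimum is the
#' grid point of maximal absolute effect size within the significant area
#' (none when the mask is empty).
#'
#' @param landscapes list of \linkS4class{GoFLandscape} objects (or plain
#'   matrices), one per subject, sharing the grid.
#' @param labels character vector of group labels (HC/PD) aligned with
#'   \code{landscapes}.
#' @param alpha family-wise significance level.
#' @param fwhm smoothing kernel FWHM in grid steps.
#' @param grid required when landscapes are plain matrices.
#' @return a \linkS4class{GroupDifferenceMap}.
#' @export
behaviouralFit <- function(landscapes, labels, alpha = 0.05, fwhm = 3,
                           grid = NULL) {
  if (is(landscapes[[1]], "GoFLandscape")) {
    if (is.null(grid)) grid <- landscapes[[1]]@grid
    mats <- lapply(landscapes, function(l) l@values)
  } else {
    if (is.null(grid)) stop("grid required for plain matrices")
    mats <- landscapes
  }
  labels <- as.character(labels)
  if (length(labels) != length(mats)) stop("labels must match landscapes")
  if (sum(labels == "HC") < 2 || sum(labels == "PD") < 2)
    stop("need at least 2 subjects per group")
  dims <- dim(mats[[1]])
  flat <- t(vapply(mats, as.vector, numeric(prod(dims))))
  zFlat <- .ranksumZColumns(flat[labels == "HC", , drop = FALSE],
                            flat[labels == "PD", , drop = FALSE])
  n <- length(labels)
  zMap <- matrix(zFlat, dims[1], dims[2])
  pMap <- matrix(pmin(1, 2 * pnorm(-abs(zFlat))), dims[1], dims[2])
  effect <- zMap / sqrt(n)
  sm <- .smoothStandardise(zMap, fwhm)
  u <- rftThreshold(dims, fwhm, alpha, twoTailed = TRUE)
  mask <- abs(sm$standardised) >= u
  optimum <- integer(0)
  if (any(mask)) {
    cand <- which(mask, arr.ind = TRUE)
    best <- cand[which.max(abs(effect[cand])), ]
    optimum <- as.integer(best)
  }
  new("GroupDifferenceMap", effectSize = effect, zMap = zMap, pMap = pMap,
      smoothedZ = sm$standardised, mask = mask, threshold = u,
      optimum = optimum, grid = grid)
}

#' Stability of behavioural optima under subsampling
#'
#' Repeats sex-balanced stratified subsampling (default 36 + 36 subjects),
#' runs the behavioural model fitting on each subsample's landscapes, and
#' collects the optima; iterations with an empty significance mask are
#' recorded with NA indices.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param landscapes named list (by subject id) of \linkS4class{GoFLandscape}
#'   objects or plain matrices (shared grid).
#' @param nIter number of subsampling iterations.
#' @param nPerGroup subjects sampled per group (default 36).
#' @param alpha,fwhm see \code{\link{behaviouralFit}}.
#' @param grid required for plain matrices.
#' @param seed master seed; iteration i uses a derived sub-seed.
#' @return data.frame with columns iter, couplingIndex, delayIndex, c, tau,
#'   effectSize (NA rows for empty masks).
#' @export
subsampleStability <- function(cohort, landscapes, nIter = 1000,
                               nPerGroup = 36, alpha = 0.05, fwhm = 3,
                               grid = NULL, seed = 1) {
  s <- subjectTable(cohort)
  if (is.null(grid)) {
    first <- landscapes[[1]]
    grid <- if (is(first, "GoFLandscape")) first@grid else
      stop("grid required for plain matrices")
  }
  out <- vector("list", nIter)
  for (it in seq_len(nIter)) {
    sub <- stratifiedSubsample(cohort, nPerGroup, seed = .subSeed(seed, "iter", it))
    ss <- subjectTable(sub)
    fit <- behaviouralFit(landscapes[ss$id], ss$group, alpha = alpha,
                          fwhm = fwhm, grid = grid)
    if (length(fit@optimum) == 2L) {
      i <- fit@optimum
      out[[it]] <- data.frame(iter = it, couplingIndex = i[1],
                              delayIndex = i[2], c = grid@cValues[i[1]],
                              tau = grid@tauValues[i[2]],
                              effectSize = fit@effectSize[i[1], i[2]])
    } else {
      out[[it]] <- data.frame(iter = it, couplingIndex = NA_integer_,
                              delayIndex = NA_integer_, c = NA_real_,
                              tau = NA_real_, effectSize = NA_real_)
    }
  }
  do.call(rbind, out)
}
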