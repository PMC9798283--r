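# Stable sub-seed derivation: one master seed, per-entity seeds obtained by
# hashing a text tag, so cohorts are reproducible piecewise.
.subSeed <- function(seed, ...) {
  tag <- paste(..., sep = "/")
  h <- as.double(seed) %% 2147483629
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Synthetic-cohort configuration
#'
#' Constructor for \linkS4class{SyntheticConfig}.  Defaults describe the
#' emulated study cohort: 51 HC / 65 PD, HC ages N(55.02, 9.69^2) and PD ages
#' N(62.00, 9.62^2) truncated at 18 years, male proportions 30/51 (HC) and
#' 45/65 (PD), 663 s scans at TR 2.21 s, and path lengths inside the
#' tractography limits [2.5, 250] mm.  \code{groundTruth} holds the hidden
#' per-group (C, tauGlobal) at which "empirical" BOLD is generated, so that
#' group differences are planted and recoverable downstream.
#'
#' @param nHC,nPD group sizes.
#' @param ageParams list with HC and PD entries, each c(mean, sd) in years.
#' @param ageFloor truncation floor for ages, years.
#' @param maleProportion named vector of male proportions per group.
#' @param nRegions regions per connectome (114 emulates a 100-parcel
#'   functional atlas plus 14 subcortical regions; 82 a 68-parcel anatomical
#'   atlas plus subcortex).
#' @param scDensity expected fraction of connected region pairs.
#' @param scMeanlog,scDispersion log-normal parameters of streamline counts.
#' @param plBounds path-length bounds in mm.
#' @param groundTruth list with HC and PD entries, each c(C, tau).
#' @param measurementNoiseSd additive Gaussian noise SD on the (unit-variance)
#'   generated BOLD.
#' @param duration scan duration, s.
#' @param tr repetition time, s.
#' @param dt neural integration step, s.
#' @param transient discarded initial time, s.
#' @param seed master seed.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nHC = 51, nPD = 65,
                            ageParams = list(HC = c(mean = 55.02, sd = 9.69),
                                             PD = c(mean = 62.00, sd = 9.62)),
                            ageFloor = 18,
                            maleProportion = c(HC = 30 / 51, PD = 45 / 65),
                            nRegions = 114, scDensity = 0.35,
                            scMeanlog = 4, scDispersion = 1,
                            plBounds = c(2.5, 250),
                            groundTruth = list(HC = c(C = 64, tau = 0.168),
                                               PD = c(C = 80, tau = 0.21)),
                            measurementNoiseSd = 0.1,
                            duration = 663, tr = 2.21, dt = 1e-3,
                            transient = 20, seed = 1L) {
  new("SyntheticConfig", nHC = as.integer(nHC), nPD = as.integer(nPD),
      ageParams = ageParams, ageFloor = ageFloor,
      maleProportion = maleProportion, nRegions = as.integer(nRegions),
      scDensity = scDensity, scMeanlog = scMeanlog,
      scDispersion = scDispersion, plBounds = plBounds,
      groundTruth = groundTruth, measurementNoiseSd = measurementNoiseSd,
      duration = duration, tr = tr, dt = dt, transient = transient,
      seed = as.integer(seed))
}

#' Construct a cohort from a subject table
#'
#' @param subjects data.frame with columns id, group, sex, age.
#' @return a \linkS4class{Cohort}.
#' @export
makeCohort <- function(subjects) {
  subjects$id <- as.character(subjects$id)
  subjects$group <- as.character(subjects$group)
  subjects$sex <- as.character(subjects$sex)
  rownames(subjects) <- NULL
  new("Cohort", subjects = subjects)
}

#' Generate cohort demography
#'
#' Draws a cohort of nHC + nPD subjects.  Ages come from the configured
#' per-group normal distributions truncated (by redrawing) at the age floor;
#' sexes are assigned by the configured per-group male proportions.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param seed integer seed (default: the config's master seed).
#' @return a \linkS4class{Cohort}; HC subjects first, then PD, each block in
#'   generation order.
#' @export
generateDemography <- function(config, seed = config@seed) {
  if (config@nHC < 0 || config@nPD < 0) stop("group sizes must be >= 0")
  set.seed(.subSeed(seed, "demography"))
  rows <- list()
  for (grp in c("HC", "PD")) {
    n <- if (grp == "HC") config@nHC else config@nPD
    if (n == 0) next
    ap <- config@ageParams[[grp]]
    ages <- rnorm(n, ap["mean"], ap["sd"])
    while (any(bad <- ages < config@ageFloor))
      ages[bad] <- rnorm(sum(bad), ap["mean"], ap["sd"])
    male <- runif(n) < config@maleProportion[[grp]]
    rows[[grp]] <- data.frame(
      id = sprintf("%s%03d", tolower(grp), seq_len(n)),
      group = grp, sex = ifelse(male, "M", "F"), age = ages,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), group = character(), sex = character(),
               age = numeric())
  makeCohort(tab)
}

#' Generate a synthetic structural connectome
#'
#' Samples a symmetric non-negative integer streamline-count matrix with zero
#' diagonal: each region pair is connected with probability
#' \code{scDensity}, and present edges carry log-normally distributed counts
#' (heavy-tailed, as empirical streamline counts are) rounded up to at least
#' one streamline.  Path lengths for present edges are drawn from a gamma
#' distribution (shape 3, mean 90 mm) truncated to \code{plBounds}.
#' Deterministic given the seed and subject id.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param subjectId subject identifier (enters the sub-seed).
#' @param seed integer master seed (default: the config's).
#' @return a \linkS4class{StructuralConnectome}.
#' @export
generateConnectome <- function(config, subjectId, seed = config@seed) {
  N <- config@nRegions
  if (N < 2) stop("nRegions must be >= 2")
  set.seed(.subSeed(seed, "connectome", subjectId))
  nPairs <- N * (N - 1) / 2
  present <- runif(nPairs) < config@scDensity
  if (!any(present)) present[sample.int(nPairs, 1)] <- TRUE
  counts <- numeric(nPairs)
  counts[present] <- pmax(1, round(rlnorm(sum(present), config@scMeanlog,
                                          config@scDispersion)))
  lens <- numeric(nPairs)
  raw <- stats::rgamma(sum(present), shape = 3, scale = 30)
  raw <- pmin(pmax(raw, config@plBounds[1]), config@plBounds[2])
  lens[present] <- raw
  sc <- matrix(0, N, N); pl <- matrix(0, N, N)
  sc[upper.tri(sc)] <- counts
  pl[upper.tri(pl)] <- lens
  sc <- sc + t(sc); pl <- pl + t(pl)
  new("StructuralConnectome", sc = sc, pl = pl)
}

#' Generate "empirical" BOLD for a subject
#'
#' Runs the forward model (neural-mass network plus Balloon-Windkessel) at
#' the hidden ground-truth (C, tauGlobal) of the subject's group, normalises
#' each regional BOLD signal to unit variance (percent-signal-change style
#' normalisation; functional connectivity is scale-invariant), and adds
#' independent Gaussian measurement noise of the configured SD.  With zero
#' noise the output equals the noiseless forward-model BOLD exactly.
#'
#' @param subject one-row data.frame (a row of \code{subjectTable}) or a
#'   list with \code{id} and \code{group}.
#' @param connectome the subject's \linkS4class{StructuralConnectome}.
#' @param config a \linkS4class{SyntheticConfig}.
#' @param seed integer master seed (default: the config's).
#' @return a \linkS4class{BoldTimeSeries} with floor(duration/tr) samples.
#' @export
generateEmpiricalBold <- function(subject, connectome, config,
                                  seed = config@seed) {
  grp <- subject$group
  gt <- config@groundTruth[[grp]]
  if (is.null(gt)) stop(sprintf("no ground truth configured for group %s", grp))
  simSeed <- .subSeed(seed, "bold", subject$id)
  ts <- simulateBold(connectome, C = gt[["C"]], tauGlobal = gt[["tau"]],
                     duration = config@duration, tr = config@tr,
                     dt = config@dt, seed = simSeed,
                     transient = config@transient)
  vals <- ts@values
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, sd)
  sdv[sdv == 0] <- 1
  vals <- (vals - mu) / sdv
  if (config@measurementNoiseSd > 0) {
    set.seed(.subSeed(seed, "noise", subject$id))
    vals <- vals + matrix(rnorm(length(vals), 0, config@measurementNoiseSd),
                          nrow = nrow(vals))
  }
  new("BoldTimeSeries", values = vals, tr = config@tr, band = "NF")
}

#' Age-balanced subset
#'
#' Removes the k oldest patients (PD) from a cohort, leaving controls
#' untouched; ties in age are broken by subject order.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param k number of oldest patients to drop.
#' @return the reduced \linkS4class{Cohort} (original subject order).
#' @export
balancedSubset <- function(cohort, k) {
  s <- subjectTable(cohort)
  pd <- which(s$group == "PD")
  if (k > length(pd)) stop("k exceeds the number of patients")
  if (k == 0) return(cohort)
  drop <- pd[order(-s$age[pd], pd)][seq_len(k)]
  makeCohort(s[-drop, , drop = FALSE])
}

#' Sex-balanced stratified subsample
#'
#' Samples n subjects per group without replacement, matching each group's
#' sex proportions as closely as integers allow (largest-remainder rounding
#' on the male count).  Deterministic given the seed.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param nPerGroup subjects per group.
#' @param seed integer seed.
#' @return the subsampled \linkS4class{Cohort} (original subject order).
#' @export
stratifiedSubsample <- function(cohort, nPerGroup, seed = 1) {
  s <- subjectTable(cohort)
  set.seed(.subSeed(seed, "subsample"))
  keep <- integer(0)
  for (grp in c("HC", "PD")) {
    gi <- which(s$group == grp)
    if (length(gi) < nPerGroup)
      stop(sprintf("group %s has fewer than %d members", grp, nPerGroup))
    mi <- gi[s$sex[gi] == "M"]; fi <- gi[s$sex[gi] == "F"]
    nM <- round(nPerGroup * length(mi) / length(gi))
    nM <- min(max(nM, nPerGroup - length(fi)), length(mi), nPerGroup)
    nF <- nPerGroup - nM
    keep <- c(keep,
              if (nM > 0) sample(mi, nM) else integer(0),
              if (nF > 0) sample(fi, nF) else integer(0))
  }
  makeCohort(s[sort(keep), , drop = FALSE])
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: demography plus per-subject connectomes and
#' "empirical" BOLD.  All randomness derives from the master seed via stable
#' per-subject sub-seeds.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param seed master seed (default: the config's).
#' @param withBold also generate empirical BOLD (the expensive part).
#' @return list with \code{cohort}, \code{connectomes} (named list) and,
#'   if requested, \code{bold} (named list of \linkS4class{BoldTimeSeries}).
#' @export
generateCohortData <- function(config, seed = config@seed, withBold = TRUE) {
  cohort <- generateDemography(config, seed)
  s <- subjectTable(cohort)
  connectomes <- lapply(seq_len(nrow(s)), function(i)
    generateConnectome(config, s$id[i], seed))
  names(connectomes) <- s$id
  out <- list(cohort = cohort, connectomes = connectomes)
  if (withBold) {
    out$bold <- lapply(seq_len(nrow(s)), function(i)
      generateEmpiricalBold(s[i, ], connectomes[[i]], config, seed))
    names(out$bold) <- s$id
  }
  out
}
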