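#' @useDynLib dynconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor pnorm qnorm pchisq rnorm runif rlnorm rbinom sd
#'   var median quantile approx uniroot fft plogis setNames complete.cases
#' @importFrom utils head read.csv write.csv
NULL

.GROUPS <- c("HC", "PD")
.SEXES <- c("F", "M")
.BANDS <- c("NF", "BF", "LF", "HF")
.RELATIONSHIPS <- c("eFC-sFC", "eSC-sFC")

#' Cohort of subjects
#'
#' Ordered collection of subjects with group (healthy control \code{HC} or
#' patient \code{PD}), sex and age.  Subject order is stable and defines row
#' order in every downstream matrix and feature table.
#'
#' @slot subjects data.frame with columns \code{id}, \code{group}, \code{sex},
#'   \code{age}.
#' @export
setClass("Cohort", representation(subjects = "data.frame"))

setValidity("Cohort", function(object) {
  s <- object@subjects
  need <- c("id", "group", "sex", "age")
  if (!all(need %in% names(s)))
    return(sprintf("subjects must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(s$id)) return("subject ids must be unique")
  if (nrow(s) && !all(s$group %in% .GROUPS)) return("group must be HC or PD")
  if (nrow(s) && !all(s$sex %in% .SEXES)) return("sex must be F or M")
  if (nrow(s) && !all(is.finite(s$age) & s$age > 0)) return("ages must be positive")
  TRUE
})

#' Structural connectome
#'
#' Streamline-count matrix (SC) and average path-length matrix (PL, mm)
#' between parcellated brain regions.  Both matrices are symmetric with zero
#' diagonal; path lengths are zero exactly where no streamline connects two
#' regions.
#'
#' @slot sc numeric matrix of non-negative streamline counts.
#' @slot pl numeric matrix of average path lengths in mm.
#' @export
setClass("StructuralConnectome", representation(sc = "matrix", pl = "matrix"))

setValidity("StructuralConnectome", function(object) {
  sc <- object@sc; pl <- object@pl
  if (nrow(sc) != ncol(sc)) return("sc must be square")
  if (!identical(dim(sc), dim(pl))) return("sc and pl must have the same shape")
  if (nrow(sc) < 2) return("connectome needs at least 2 regions")
  if (any(!is.finite(sc)) || any(!is.finite(pl))) return("non-finite entries")
  if (any(sc < 0)) return("sc must be non-negative")
  if (any(pl < 0)) return("pl must be non-negative")
  if (max(abs(sc - t(sc))) > 0) return("sc must be symmetric")
  if (max(abs(pl - t(pl))) > 0) return("pl must be symmetric")
  if (any(diag(sc) != 0) || any(diag(pl) != 0)) return("diagonals must be zero")
  if (any(pl[sc == 0] != 0)) return("pl must be 0 where sc is 0")
  off <- sc > 0
  if (any(pl[off] <= 0)) return("pl must be positive where sc is positive")
  TRUE
})

#' Regional BOLD time series
#'
#' Region-by-time matrix of BOLD samples with the repetition time and the
#' frequency-band tag of any filtering already applied (\code{NF} means
#' unfiltered).
#'
#' @slot values numeric matrix, regions in rows, time points in columns.
#' @slot tr repetition time in seconds.
#' @slot band one of \code{NF}, \code{BF}, \code{LF}, \code{HF}.
#' @export
setClass("BoldTimeSeries",
         representation(values = "matrix", tr = "numeric", band = "character"))

setValidity("BoldTimeSeries", function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  if (ncol(object@values) < 2) return("need at least 2 time points")
  if (length(object@tr) != 1 || object@tr <= 0) return("tr must be a positive scalar")
  if (!(object@band %in% .BANDS)) return("band must be NF, BF, LF or HF")
  TRUE
})

#' Functional connectome
#'
#' Pearson correlation matrix between regional BOLD time series, with the
#' filtering band and the data source (empirical or simulated).
#'
#' @slot values symmetric correlation matrix with unit diagonal.
#' @slot band frequency-band tag.
#' @slot source \code{"empirical"} or \code{"simulated"}.
#' @export
setClass("FunctionalConnectome",
         representation(values = "matrix", band = "character", source = "character"))

setValidity("FunctionalConnectome", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("must be square")
  if (any(!is.finite(v))) return("non-finite entries")
  if (max(abs(v - t(v))) > 1e-10) return("must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-10) return("diagonal must be 1")
  if (any(v < -1 - 1e-10 | v > 1 + 1e-10)) return("entries must be in [-1, 1]")
  if (!(object@band %in% .BANDS)) return("band must be NF, BF, LF or HF")
  if (!(object@source %in% c("empirical", "simulated")))
    return("source must be empirical or simulated")
  TRUE
})

#' Neural-mass model parameters
#'
#' Parameters of the two-population (excitatory/inhibitory) convolution-based
#' neural-mass model.  Defaults are the standard values for this model family:
#' maximal firing densities \code{Fe} = 100 and \code{Fi} = 50 1/s, kernel
#' rate constants \code{a} = 100 and \code{b} = 50 1/s, kernel amplitudes
#' \code{A} = 3.25 and \code{B} = 22 mV, sigmoid slope \code{r} = 0.56 1/mV,
#' half-activation potential \code{v0} = 6 mV, intra-regional couplings
#' \code{Cie} = \code{Cei} = 6, frequency scaling factor \code{R} = 2.2, and
#' bounded uniform noise of amplitude 1.5 V/s^2 on the current derivatives.
#'
#' @export
setClass("NeuralMassParams",
         representation(Fe = "numeric", Fi = "numeric", a = "numeric",
                        b = "numeric", A = "numeric", B = "numeric",
                        r = "numeric", v0 = "numeric", Cie = "numeric",
                        Cei = "numeric", R = "numeric",
                        noiseAmplitude = "numeric"))

setValidity("NeuralMassParams", function(object) {
  vals <- c(object@Fe, object@Fi, object@a, object@b, object@A, object@B,
            object@r, object@v0, object@Cie, object@Cei, object@R)
  if (any(!is.finite(vals)) || any(vals <= 0)) return("all parameters must be positive")
  if (!is.finite(object@noiseAmplitude) || object@noiseAmplitude < 0)
    return("noiseAmplitude must be non-negative")
  TRUE
})

#' Balloon-Windkessel hemodynamic parameters
#'
#' Parameters of the hemodynamic model converting neural activity to BOLD:
#' echo time \code{TE} = 0.030 s, mean transit time \code{tMTT} = 2 s,
#' resting oxygen extraction \code{E0} = 0.4, resting venous volume fraction
#' \code{V0} = 0.04, frequency offset \code{theta0} = 80.6 1/s,
#' intra/extra-vascular signal ratio \code{epsilon} = 0.3, sensitivity slope
#' \code{r0} = 25 1/s, flow-volume exponent \code{alpha} = 0.38 and rate
#' constants \code{kappa} = 0.64, \code{gamma} = 0.32 Hz.
#'
#' @export
setClass("BWParams",
         representation(TE = "numeric", tMTT = "numeric", E0 = "numeric",
                        V0 = "numeric", theta0 = "numeric", epsilon = "numeric",
                        r0 = "numeric", alpha = "numeric", kappa = "numeric",
                        gamma = "numeric"))

setValidity("BWParams", function(object) {
  vals <- c(object@TE, object@tMTT, object@E0, object@V0, object@theta0,
            object@epsilon, object@r0, object@alpha, object@kappa, object@gamma)
  if (any(!is.finite(vals)) || any(vals <= 0)) return("all parameters must be positive")
  if (object@E0 >= 1) return("E0 must be in (0, 1)")
  if (object@alpha >= 1) return("alpha must be in (0, 1)")
  TRUE
})

#' Parameter grid for model fitting
#'
#' Ordered global-coupling values and global-delay values (s/m) defining the
#' rectangular grid scanned during model validation.
#'
#' @slot cValues strictly increasing global couplings.
#' @slot tauValues strictly increasing global delays in s/m.
#' @export
setClass("ParameterGrid",
         representation(cValues = "numeric", tauValues = "numeric"))

setValidity("ParameterGrid", function(object) {
  if (!length(object@cValues) || !length(object@tauValues))
    return("grid axes must be non-empty")
  if (any(!is.finite(object@cValues)) || any(!is.finite(object@tauValues)))
    return("grid axes must be finite")
  if (is.unsorted(object@cValues, strictly = TRUE))
    return("cValues must be strictly increasing")
  if (is.unsorted(object@tauValues, strictly = TRUE))
    return("tauValues must be strictly increasing")
  if (any(object@cValues < 0) || any(object@tauValues < 0))
    return("grid values must be non-negative")
  TRUE
})

#' Goodness-of-fit landscape
#'
#' Per-subject Pearson correlations between an empirical connectome (eFC or
#' eSC) and the simulated FC at every point of the parameter grid.
#'
#' @slot subject subject identifier.
#' @slot relationship \code{"eFC-sFC"} or \code{"eSC-sFC"}.
#' @slot band frequency-band tag.
#' @slot atlas parcellation label.
#' @slot values matrix (couplings in rows, delays in columns) of correlations.
#' @slot grid the \linkS4class{ParameterGrid}.
#' @export
setClass("GoFLandscape",
         representation(subject = "character", relationship = "character",
                        band = "character", atlas = "character",
                        values = "matrix", grid = "ParameterGrid"))

setValidity("GoFLandscape", function(object) {
  g <- object@grid
  if (!identical(dim(object@values),
                 c(length(g@cValues), length(g@tauValues))))
    return("values shape must match grid (couplings x delays)")
  v <- object@values
  if (any(!is.finite(v))) return("landscape has non-finite values")
  if (any(v < -1 - 1e-10 | v > 1 + 1e-10)) return("values must be in [-1, 1]")
  if (!(object@relationship %in% .RELATIONSHIPS))
    return("relationship must be eFC-sFC or eSC-sFC")
  if (!(object@band %in% .BANDS)) return("band must be NF, BF, LF or HF")
  TRUE
})

#' Group-difference map from behavioural model fitting
#'
#' Per grid point: rank-sum z and two-tail p between the groups' GoF values,
#' the signed effect size (z divided by the square root of the number of
#' observations, positive for HC > PD), the smoothed and variance-standardised
#' z map, the significance mask after random-field thresholding, and the
#' optimum (grid indices of maximal absolute effect size inside the mask;
#' length-0 when the mask is empty).
#'
#' @export
setClass("GroupDifferenceMap",
         representation(effectSize = "matrix", zMap = "matrix", pMap = "matrix",
                        smoothedZ = "matrix", mask = "matrix",
                        threshold = "numeric", optimum = "integer",
                        grid = "ParameterGrid"))

setValidity("GroupDifferenceMap", function(object) {
  dims <- dim(object@zMap)
  for (nm in c("effectSize", "pMap", "smoothedZ", "mask"))
    if (!identical(dim(slot(object, nm)), dims))
      return(sprintf("%s shape differs from zMap", nm))
  if (any(object@pMap < 0 | object@pMap > 1)) return("p values must be in [0, 1]")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!(length(object@optimum) %in% c(0L, 2L)))
    return("optimum must be empty or two grid indices")
  if (length(object@optimum) == 2L && !object@mask[object@optimum[1], object@optimum[2]])
    return("optimum must lie inside the significance mask")
  TRUE
})

#' Synthetic-cohort configuration
#'
#' All knobs of the synthetic-cohort generator: group sizes and demography,
#' connectome sampling, ground-truth model parameters per group used to
#' generate "empirical" BOLD, measurement noise, scan duration and TR.  The
#' defaults emulate the study conditions of a two-group clinical resting-state
#' cohort: 51 controls / 65 patients, control ages N(55.02, 9.69^2) and
#' patient ages N(62.00, 9.62^2) truncated at 18 years, male proportions
#' 30/51 and 45/65, path lengths bounded by the tractography limits
#' 2.5--250 mm, scans of 663 s at TR 2.21 s.
#'
#' @export
setClass("SyntheticConfig",
         representation(nHC = "integer", nPD = "integer", ageParams = "list",
                        ageFloor = "numeric", maleProportion = "numeric",
                        nRegions = "integer", scDensity = "numeric",
                        scMeanlog = "numeric", scDispersion = "numeric",
                        plBounds = "numeric", groundTruth = "list",
                        measurementNoiseSd = "numeric", duration = "numeric",
                        tr = "numeric", dt = "numeric", transient = "numeric",
                        seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@nHC < 0 || object@nPD < 0) return("group sizes must be >= 0")
  if (!all(c("HC", "PD") %in% names(object@ageParams)))
    return("ageParams needs HC and PD entries")
  if (object@tr <= 0 || object@tr >= object@duration)
    return("need 0 < tr < duration")
  if (length(object@plBounds) != 2 || object@plBounds[1] <= 0 ||
      object@plBounds[2] <= object@plBounds[1])
    return("plBounds must be increasing and positive")
  if (object@scDensity <= 0 || object@scDensity > 1)
    return("scDensity must be in (0, 1]")
  if (object@nRegions < 2) return("nRegions must be >= 2")
  if (object@measurementNoiseSd < 0) return("measurementNoiseSd must be >= 0")
  TRUE
})
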