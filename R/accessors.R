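#' @name accessors
#' @title Accessors for dynconn containers
#' @description Small accessor generics so user code never touches slots
#'   directly.
#' @param object a dynconn S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("scMatrix", function(object) standardGeneric("scMatrix"))
#' @rdname accessors
#' @export
setGeneric("plMatrix", function(object) standardGeneric("plMatrix"))
#' @rdname accessors
#' @export
setGeneric("tsValues", function(object) standardGeneric("tsValues"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("bandName", function(object) standardGeneric("bandName"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(object) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("subjectTable", function(object) standardGeneric("subjectTable"))
#' @rdname accessors
#' @export
setGeneric("gofValues", function(object) standardGeneric("gofValues"))
#' @rdname accessors
#' @export
setGeneric("gridCouplings", function(object) standardGeneric("gridCouplings"))
#' @rdname accessors
#' @export
setGeneric("gridDelays", function(object) standardGeneric("gridDelays"))
#' @rdname accessors
#' @export
setGeneric("significanceMask", function(object) standardGeneric("significanceMask"))
#' @rdname accessors
#' @export
setGeneric("effectSizeMap", function(object) standardGeneric("effectSizeMap"))
#' @rdname accessors
#' @export
setGeneric("fitOptimum", function(object) standardGeneric("fitOptimum"))

#' @rdname accessors
setMethod("nRegions", "StructuralConnectome", function(object) nrow(object@sc))
#' @rdname accessors
setMethod("scMatrix", "StructuralConnectome", function(object) object@sc)
#' @rdname accessors
setMethod("plMatrix", "StructuralConnectome", function(object) object@pl)
#' @rdname accessors
setMethod("nRegions", "BoldTimeSeries", function(object) nrow(object@values))
#' @rdname accessors
setMethod("tsValues", "BoldTimeSeries", function(object) object@values)
#' @rdname accessors
setMethod("repetitionTime", "BoldTimeSeries", function(object) object@tr)
#' @rdname accessors
setMethod("bandName", "BoldTimeSeries", function(object) object@band)
#' @rdname accessors
setMethod("fcValues", "FunctionalConnectome", function(object) object@values)
#' @rdname accessors
setMethod("bandName", "FunctionalConnectome", function(object) object@band)
#' @rdname accessors
setMethod("nRegions", "FunctionalConnectome", function(object) nrow(object@values))
#' @rdname accessors
setMethod("subjectTable", "Cohort", function(object) object@subjects)
#' @rdname accessors
setMethod("gofValues", "GoFLandscape", function(object) object@values)
#' @rdname accessors
setMethod("gridCouplings", "ParameterGrid", function(object) object@cValues)
#' @rdname accessors
setMethod("gridDelays", "ParameterGrid", function(object) object@tauValues)
#' @rdname accessors
setMethod("gridCouplings", "GoFLandscape", function(object) object@grid@cValues)
#' @rdname accessors
setMethod("gridDelays", "GoFLandscape", function(object) object@grid@tauValues)
#' @rdname accessors
setMethod("significanceMask", "GroupDifferenceMap", function(object) object@mask)
#' @rdname accessors
setMethod("effectSizeMap", "GroupDifferenceMap", function(object) object@effectSize)
#' @rdname accessors
setMethod("fitOptimum", "GroupDifferenceMap", function(object) object@optimum)

setMethod("show", "Cohort", function(object) {
  s <- object@subjects
  cat(sprintf("Cohort: %d subjects (%d HC, %d PD)\n", nrow(s),
              sum(s$group == "HC"), sum(s$group == "PD")))
  if (nrow(s))
    cat(sprintf("  ages %.1f-%.1f (mean %.1f)\n", min(s$age), max(s$age),
                mean(s$age)))
})

setMethod("show", "StructuralConnectome", function(object) {
  sc <- object@sc
  dens <- mean(sc[upper.tri(sc)] > 0)
  cat(sprintf("StructuralConnectome: %d regions, density %.2f, mean count %.1f\n",
              nrow(sc), dens, mean(sc[upper.tri(sc)])))
})

setMethod("show", "BoldTimeSeries", function(object) {
  cat(sprintf("BoldTimeSeries: %d regions x %d samples, TR %.3g s, band %s\n",
              nrow(object@values), ncol(object@values), object@tr, object@band))
})

setMethod("show", "FunctionalConnectome", function(object) {
  v <- object@values
  cat(sprintf("FunctionalConnectome (%s, band %s): %d regions, mean off-diag r %.3f\n",
              object@source, object@band, nrow(v), mean(v[upper.tri(v)])))
})

setMethod("show", "ParameterGrid", function(object) {
  cat(sprintf("ParameterGrid: %d couplings in [%g, %g] x %d delays in [%g, %g] s/m\n",
              length(object@cValues), min(object@cValues), max(object@cValues),
              length(object@tauValues), min(object@tauValues), max(object@tauValues)))
})

setMethod("show", "GoFLandscape", function(object) {
  cat(sprintf("GoFLandscape (%s, band %s, atlas %s) subject %s: %dx%d, max %.3f\n",
              object@relationship, object@band, object@atlas, object@subject,
              nrow(object@values), ncol(object@values), max(object@values)))
})

setMethod("show", "GroupDifferenceMap", function(object) {
  cat(sprintf("GroupDifferenceMap: %dx%d grid, |z| threshold %.2f, %d significant points\n",
              nrow(object@zMap), ncol(object@zMap), object@threshold,
              sum(object@mask)))
  if (length(object@optimum) == 2L) {
    i <- object@optimum
    cat(sprintf("  optimum: C = %g, tau = %g s/m (effect size %.3f)\n",
                object@grid@cValues[i[1]], object@grid@tauValues[i[2]],
                object@effectSize[i[1], i[2]]))
  } else cat("  optimum: none (empty mask)\n")
})

setMethod("show", "NeuralMassParams", function(object) {
  cat(sprintf(paste0("NeuralMassParams: Fe=%g Fi=%g a=%g b=%g A=%g B=%g r=%g ",
                     "v0=%g Cie=%g Cei=%g R=%g noise=%g\n"),
              object@Fe, object@Fi, object@a, object@b, object@A, object@B,
              object@r, object@v0, object@Cie, object@Cei, object@R,
              object@noiseAmplitude))
})

setMethod("show", "BWParams", function(object) {
  cat(sprintf(paste0("BWParams: TE=%g tMTT=%g E0=%g V0=%g theta0=%g eps=%g ",
                     "r0=%g alpha=%g kappa=%g gamma=%g\n"),
              object@TE, object@tMTT, object@E0, object@V0, object@theta0,
              object@epsilon, object@r0, object@alpha, object@kappa,
              object@gamma))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d HC + %d PD, %d regions, %g s at TR %g s,\n",
                     "  SC density %.2f, PL in [%g, %g] mm, noise sd %g\n"),
              object@nHC, object@nPD, object@nRegions, object@duration,
              object@tr, object@scDensity, object@plBounds[1],
              object@plBounds[2], object@measurementNoiseSd))
})
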