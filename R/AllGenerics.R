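#' Accessors for mixscreen classes
#'
#' `nuclearChannel`/`markerChannel` return the intensity matrices of a
#' [FieldImage-class]; `ic50`, `hillSlope` and `isConverged` read the fitted
#' parameters of a [DRFit-class].
#'
#' @param object a `FieldImage` or `DRFit` object.
#' @return matrix, numeric or logical scalar, respectively.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nuclearChannel", function(object) standardGeneric("nuclearChannel"))

#' @rdname accessors
#' @export
setGeneric("markerChannel", function(object) standardGeneric("markerChannel"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
setMethod("nuclearChannel", "FieldImage", function(object) object@nuclear)

#' @rdname accessors
setMethod("markerChannel", "FieldImage", function(object) object@marker)

#' @rdname accessors
setMethod("ic50", "DRFit", function(object) object@ic50)

#' @rdname accessors
setMethod("hillSlope", "DRFit", function(object) object@hill)

#' @rdname accessors
setMethod("isConverged", "DRFit", function(object) object@converged)

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@nuclear)
  cat(sprintf("FieldImage well %s site %d: %d x %d px, %d-bit\n",
              object@well, object@site, d[1], d[2], object@bitDepth))
  cat(sprintf("  nuclear range [%.0f, %.0f], marker range [%.0f, %.0f]\n",
              min(object@nuclear), max(object@nuclear),
              min(object@marker), max(object@marker)))
})

setMethod("show", "PopulationParams", function(object) {
  cat(sprintf("PopulationParams '%s': n0 = %g, doubling time = %g h%s\n",
              object@name, object@n0, object@doublingTime,
              if (object@markerPositive) ", CK8/18+" else ", CK8/18-"))
  if (object@drugSensitive)
    cat(sprintf("  drug-sensitive: IC50 = %g nM, hill = %g, emax = %g\n",
                object@ic50, object@hill, object@emax))
  else cat("  drug-insensitive\n")
})

setMethod("show", "DRFit", function(object) {
  cat(sprintf("DRFit [%s, %s]\n", object@drug, object@population))
  if (object@converged) {
    cat(sprintf("  IC50 = %.3g nM (95%% CI %.3g-%.3g), hill = %.2f\n",
                object@ic50, object@ic50CI[1], object@ic50CI[2], object@hill))
    cat(sprintf("  top = %.4g, bottom = %.4g, residual SE = %.3g, n = %d\n",
                object@top, object@bottom, object@residualSE, object@n))
  } else {
    cat(sprintf("  not converged: %s\n", object@message))
  }
})

setMethod("show", "MediaScenario", function(object) {
  cat(sprintf("MediaScenario '%s': IC50 shift x%g; growth multipliers: %s\n",
              object@name, object@ic50Shift,
              paste(sprintf("%s=%g", names(object@growthMultiplier),
                            object@growthMultiplier), collapse = ", ")))
})
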