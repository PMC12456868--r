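# Generics and accessors. Slot access goes through these everywhere.

#' @rdname accessors
#' @export
setGeneric("plaquePoints", function(x) standardGeneric("plaquePoints"))
#' @rdname accessors
#' @export
setGeneric("diameters", function(x) standardGeneric("diameters"))
#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))
#' @rdname accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("axialCoords", function(x) standardGeneric("axialCoords"))
#' @rdname accessors
#' @export
setGeneric("lateralCoords", function(x) standardGeneric("lateralCoords"))
#' @rdname accessors
#' @export
setGeneric("scanLevels", function(x) standardGeneric("scanLevels"))
#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))
#' @rdname accessors
#' @export
setGeneric("scanValues", function(x) standardGeneric("scanValues"))
#' @rdname accessors
#' @export
setGeneric("prValues", function(x) standardGeneric("prValues"))
#' @rdname accessors
#' @export
setGeneric("afSlopes", function(x) standardGeneric("afSlopes"))
#' @rdname accessors
#' @export
setGeneric("afIntercepts", function(x) standardGeneric("afIntercepts"))
#' @rdname accessors
#' @export
setGeneric("cvError", function(x) standardGeneric("cvError"))
#' @rdname accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))
#' @rdname accessors
#' @export
setGeneric("axialShift", function(x) standardGeneric("axialShift"))

#' Accessors for plaquefp S4 containers
#'
#' Slot access for the package's data classes: point sets
#' (\code{plaquePoints}, \code{diameters}, \code{genotype}), depth-indexed
#' profiles (\code{depths}, \code{counts}, \code{densities}, \code{zscores},
#' \code{positions}, \code{profileValues}), 2-D/3-D fields
#' (\code{fieldValues}, \code{voltages}, \code{pixelSize},
#' \code{axialCoords}, \code{lateralCoords}), galvo-scan matrices
#' (\code{scanLevels}, \code{scanTimes}, \code{scanValues}), calibration and
#' autofluorescence models (\code{prValues}, \code{afSlopes},
#' \code{afIntercepts}, \code{cvError}) and fiber tracks
#' (\code{hemisphere}, \code{axialShift}).
#'
#' @param x an object of the matching class.
#' @return the slot contents.
#' @name accessors
#' @examples
#' pf <- makePlaqueField(50, seed = 1)
#' nrow(plaquePoints(pf))
NULL

#' @rdname accessors
setMethod("plaquePoints", "PlaqueField", function(x) x@points)
#' @rdname accessors
setMethod("diameters", "PlaqueField", function(x) x@diameters)
#' @rdname accessors
setMethod("genotype", "PlaqueField", function(x) x@genotype)

#' @rdname accessors
setMethod("depths", "DepthProfile", function(x) x@depth)
#' @rdname accessors
setMethod("counts", "DepthProfile", function(x) x@counts)
#' @rdname accessors
setMethod("densities", "DepthProfile", function(x) x@density)
#' @rdname accessors
setMethod("depths", "ZProfile", function(x) x@depth)
#' @rdname accessors
setMethod("zscores", "ZProfile", function(x) x@dF)
#' @rdname accessors
setMethod("positions", "AxialProfile", function(x) x@positions)
#' @rdname accessors
setMethod("profileValues", "AxialProfile", function(x) x@values)

#' @rdname accessors
setMethod("fieldValues", "SectionImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixelSize", "SectionImage", function(x) x@pixelUm)
#' @rdname accessors
setMethod("fieldValues", "CollectionField", function(x) x@values)
#' @rdname accessors
setMethod("pixelSize", "CollectionField", function(x) x@pixelUm)
#' @rdname accessors
setMethod("axialCoords", "CollectionField", function(x) x@axialUm)
#' @rdname accessors
setMethod("lateralCoords", "CollectionField", function(x) x@lateralUm)
#' @rdname accessors
setMethod("fieldValues", "IlluminationStack", function(x) x@values)
#' @rdname accessors
setMethod("voltages", "IlluminationStack", function(x) x@voltages)
#' @rdname accessors
setMethod("pixelSize", "IlluminationStack", function(x) x@pixelUm)
#' @rdname accessors
setMethod("axialCoords", "IlluminationStack", function(x) x@axialUm)
#' @rdname accessors
setMethod("lateralCoords", "IlluminationStack", function(x) x@lateralUm)
#' @rdname accessors
setMethod("fieldValues", "PhotometryStack", function(x) x@values)
#' @rdname accessors
setMethod("voltages", "PhotometryStack", function(x) x@voltages)
#' @rdname accessors
setMethod("pixelSize", "PhotometryStack", function(x) x@pixelUm)
#' @rdname accessors
setMethod("axialCoords", "PhotometryStack", function(x) x@axialUm)
#' @rdname accessors
setMethod("lateralCoords", "PhotometryStack", function(x) x@lateralUm)

#' @rdname accessors
setMethod("scanLevels", "GalvoScanMatrix", function(x) x@levels)
#' @rdname accessors
setMethod("scanTimes", "GalvoScanMatrix", function(x) x@times)
#' @rdname accessors
setMethod("scanValues", "GalvoScanMatrix", function(x) x@values)

#' @rdname accessors
setMethod("scanLevels", "PowerCalibration", function(x) x@levels)
#' @rdname accessors
setMethod("prValues", "PowerCalibration", function(x) x@pr)

#' @rdname accessors
setMethod("scanLevels", "AFModel", function(x) x@levels)
#' @rdname accessors
setMethod("afSlopes", "AFModel", function(x) x@slopes)
#' @rdname accessors
setMethod("afIntercepts", "AFModel", function(x) x@intercepts)
#' @rdname accessors
setMethod("cvError", "AFModel", function(x) x@cvError)

#' @rdname accessors
setMethod("hemisphere", "FiberTrack", function(x) x@hemisphere)
#' @rdname accessors
setMethod("axialShift", "FiberTrack", function(x) x@axialShiftUm)

# -- show methods -------------------------------------------------------------

setMethod("show", "PlaqueField", function(object) {
  cat(sprintf("PlaqueField: %d plaques (%s)\n", nrow(object@points),
              object@genotype))
  if (nrow(object@points)) {
    r <- range(object@points[, 3])
    cat(sprintf("  DV range %.0f-%.0f um; diameters %.1f-%.1f um\n",
                r[1], r[2], min(object@diameters), max(object@diameters)))
  }
})

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording: %d samples", length(object@t)))
  if (length(object@t))
    cat(sprintf(", t = %.3f-%.1f s", object@t[1], object@t[length(object@t)]))
  cat("\n")
})

setMethod("show", "SectionImage", function(object) {
  cat(sprintf("SectionImage: %d x %d px at %.2f um/px, AP = %.0f um\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelUm,
              object@apUm))
})

setMethod("show", "FiberTrack", function(object) {
  cat(sprintf(
    "FiberTrack (%s): AP = %.1f %+.4f*d, ML = %.1f %+.4f*d um; shift %.0f um\n",
    object@hemisphere, object@apCoef[1], object@apCoef[2], object@mlCoef[1],
    object@mlCoef[2], object@axialShiftUm))
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile: %d depths, %g plaques total (radius %.0f um)\n",
              length(object@depth), sum(object@counts), object@radiusUm))
})

setMethod("show", "ZProfile", function(object) {
  cat(sprintf("ZProfile: %d depths, baseline %.0f-%.0f um\n",
              length(object@depth), object@baselineWindowUm[1],
              object@baselineWindowUm[2]))
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix: %d samples x %d depths (%d affected, %d control)\n",
              nrow(object@values), ncol(object@values),
              sum(object@labels == "affected"),
              sum(object@labels == "control")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive class: affected)\n")
  cat(sprintf("  hits %d  misses %d  false alarms %d  correct rejections %d\n",
              object@hits, object@misses, object@falseAlarms,
              object@correctRejections))
})

setMethod("show", "IlluminationStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("IlluminationStack: %d x %d px x %d voltages (max %.3g)\n",
              d[1], d[2], d[3], max(object@values)))
})

setMethod("show", "CollectionField", function(object) {
  cat(sprintf("CollectionField: %d x %d px at %.1f um/px\n",
              nrow(object@values), ncol(object@values), object@pixelUm))
})

setMethod("show", "PhotometryStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("PhotometryStack: %d x %d px x %d voltages\n", d[1], d[2], d[3]))
})

setMethod("show", "AxialProfile", function(object) {
  cat(sprintf("AxialProfile (%s): %d positions\n", object@kind,
              length(object@positions)))
})

setMethod("show", "GalvoScanMatrix", function(object) {
  cat(sprintf("GalvoScanMatrix: %d levels x %d times (%s, %g uW)\n",
              length(object@levels), length(object@times), object@channel,
              object@powerUw))
})

setMethod("show", "AFModel", function(object) {
  cat(sprintf("AFModel: %d levels, median |a| = %.3g a.u./s, cv error %.3g\n",
              length(object@levels), median(abs(object@slopes)),
              median(object@cvError)))
})

setMethod("show", "PowerCalibration", function(object) {
  cat(sprintf("PowerCalibration: %d levels, PR range 1-%.3g\n",
              length(object@levels), max(object@pr)))
})
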