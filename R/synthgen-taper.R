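# Synthetic taper optics: illumination stacks, collection fields, and the
# galvo-voltage -> axial-position map. Fields are phenomenological (no ray
# tracing): a tapered fiber emits a narrow band of light whose axial
# position sweeps monotonically along the taper as the injection angle
# (galvo voltage) increases, and collects fluorescence with an efficiency
# that decays radially away from the fiber axis.

#' Affine galvo-voltage to axial-position map
#'
#' Voltages in \code{[galvoRangeV[1], galvoRangeV[2]]} (default 0-4.5 V)
#' map affinely onto the taper's active span; with the default
#' \code{"shallow-to-deep"} orientation 0 V addresses the shallow end and
#' 4.5 V the tip. Voltages below the range (the -1 to 0 V segment of the
#' sweep) return NA: they deliver light outside the tissue.
#'
#' @param voltagesV galvo command voltages.
#' @param geometry a \linkS4class{TaperGeometry}; NULL returns positions
#'   along the span (um from the shallow end) instead of DV depths.
#' @param galvoRangeV analysed voltage range (V).
#' @param orientation sweep direction along the taper.
#' @return axial positions (um along the span) or DV depths (um) when a
#'   geometry is supplied.
#' @export
#' @examples
#' galvoAxialUm(c(0, 2.25, 4.5))
galvoAxialUm <- function(voltagesV, geometry = NULL,
                         galvoRangeV = c(0, 4.5),
                         orientation = c("shallow-to-deep",
                                         "deep-to-shallow")) {
  orientation <- match.arg(orientation)
  .assertRange(galvoRangeV, "galvoRangeV")
  span <- if (is.null(geometry)) galvoSpanUm() else geometry@activeSpanUm
  u <- (voltagesV - galvoRangeV[1]) / diff(galvoRangeV)
  u[voltagesV < galvoRangeV[1] - 1e-12 | voltagesV > galvoRangeV[2] + 1e-12] <- NA
  if (orientation == "deep-to-shallow") u <- 1 - u
  a <- u * span
  if (is.null(geometry)) return(a)
  # DV of the point at distance (span - a) from the tip along the axis
  geometry@tip[3] + geometry@axis[3] * (span - a)
}

#' Illumination amplitude envelope over galvo voltage
#'
#' Relative light power delivered into tissue as a function of the galvo
#' voltage: near-zero at the terminal input angles and maximal mid-sweep.
#' This is the generator's stated envelope, \code{sin^2(pi * u)} with
#' \code{u} the normalized voltage; voltages outside the range get 0.
#'
#' @param voltagesV galvo voltages.
#' @param galvoRangeV analysed voltage range (V).
#' @return envelope values in [0, 1].
#' @export
illuminationEnvelope <- function(voltagesV, galvoRangeV = c(0, 4.5)) {
  u <- (voltagesV - galvoRangeV[1]) / diff(galvoRangeV)
  e <- sin(pi * pmin(pmax(u, 0), 1))^2
  e[u < 0 | u > 1] <- 0
  e
}

.taperGrid <- function(geometry, pixelUm, axialPadUm, lateralHalfUm) {
  span <- geometry@activeSpanUm
  nAx <- ceiling((span + 2 * axialPadUm) / pixelUm)
  nLat <- 2L * ceiling(lateralHalfUm / pixelUm)
  list(axialUm = -axialPadUm + (seq_len(nAx) - 0.5) * pixelUm,
       lateralUm = -lateralHalfUm + (seq_len(nLat) - 0.5) * pixelUm)
}

#' Generate a synthetic illumination stack I(x,y,V)
#'
#' Each frame is a Gaussian band of light centered at the axial position
#' mapped from its galvo voltage (see \code{\link{galvoAxialUm}}), with
#' axial sd \code{axialSigmaUm} and lateral sd \code{widthUm / 2}, scaled
#' by \code{\link{illuminationEnvelope}} so terminal voltages deliver
#' near-zero light. The stack is normalized to a global maximum of 1.
#' Optional Gaussian camera noise (clipped at 0) is added before
#' normalization.
#'
#' @param geometry a \linkS4class{TaperGeometry}.
#' @param voltagesV galvo voltages, all within \code{galvoRangeV} or the
#'   off-tissue segment down to -1 V.
#' @param widthUm lateral FWHM-scale of the band (um); the lateral Gaussian
#'   sd is \code{widthUm / 2}.
#' @param pixelUm pixel size (um).
#' @param axialSigmaUm axial sd of the band (um).
#' @param noiseSd camera noise sd relative to the band peak.
#' @param seed integer seed for the noise.
#' @param galvoRangeV analysed voltage range.
#' @param envelope amplitude envelope over voltage, a function of
#'   \code{(voltagesV, galvoRangeV)}; the default
#'   \code{\link{illuminationEnvelope}} is near-zero at the terminal
#'   angles.
#' @return an \linkS4class{IlluminationStack}; \code{meta$bandCentersUm}
#'   and \code{meta$envelope} carry the ground truth.
#' @export
makeIlluminationStack <- function(geometry, voltagesV = seq(0, 4.5,
                                    length.out = 41),
                                  widthUm = 80, pixelUm = 10,
                                  axialSigmaUm = 60, noiseSd = 0,
                                  seed = NULL, galvoRangeV = c(0, 4.5),
                                  envelope = illuminationEnvelope) {
  stopifnot(is(geometry, "TaperGeometry"))
  .assertScalar(widthUm, "widthUm", positive = TRUE)
  .assertScalar(pixelUm, "pixelUm", positive = TRUE)
  if (any(voltagesV < -1 - 1e-9) || any(voltagesV > galvoRangeV[2] + 1e-9))
    stop("voltages outside the galvo range")

  sigLat <- widthUm / 2
  grid <- .taperGrid(geometry, pixelUm, axialPadUm = 6 * axialSigmaUm,
                     lateralHalfUm = 6 * sigLat)
  centers <- galvoAxialUm(voltagesV, galvoRangeV = galvoRangeV)
  env <- envelope(voltagesV, galvoRangeV)
  latProf <- exp(-grid$lateralUm^2 / (2 * sigLat^2))
  nV <- length(voltagesV)
  arr <- array(0, c(length(grid$lateralUm), length(grid$axialUm), nV))
  for (k in seq_len(nV)) {
    if (is.na(centers[k]) || env[k] == 0) next   # off-tissue: dark frame
    axProf <- exp(-(grid$axialUm - centers[k])^2 / (2 * axialSigmaUm^2))
    arr[, , k] <- env[k] * outer(latProf, axProf)
  }
  if (noiseSd > 0) {
    arr <- arr + withSeed(seed, array(rnorm(length(arr), 0, noiseSd), dim(arr)))
    arr[arr < 0] <- 0
  }
  m <- max(arr)
  if (m <= 0) stop("stack has no light; cannot normalize")
  new("IlluminationStack", values = arr / m, voltages = as.numeric(voltagesV),
      pixelUm = pixelUm, axialUm = grid$axialUm, lateralUm = grid$lateralUm,
      meta = list(bandCentersUm = centers, envelope = env,
                  axialSigmaUm = axialSigmaUm, widthUm = widthUm,
                  noiseSd = noiseSd, seed = seed))
}

#' Generate a synthetic collection field C(x,y)
#'
#' Collection efficiency is maximal on the fiber axis and decays
#' exponentially with radial (lateral) distance,
#' \code{C(r) = exp(-r / radialDecayUm)}. A positive
#' \code{footprintRadiusUm} masks pixels within that lateral distance of
#' the axis to 0 (inside the fiber there is no tissue); the default 0
#' leaves the axis unmasked so C is strictly decreasing from its on-axis
#' maximum.
#'
#' @param geometry a \linkS4class{TaperGeometry}.
#' @param radialDecayUm exponential decay constant (um), > 0.
#' @param pixelUm pixel size (um).
#' @param like optional \linkS4class{IlluminationStack} whose pixel grid the
#'   field must share (required for \code{\link{photometryStack}}).
#' @param footprintRadiusUm fiber footprint half-width (um).
#' @param axialPadUm,lateralHalfUm grid extent when \code{like} is NULL;
#'   defaults match \code{makeIlluminationStack}'s defaults.
#' @return a \linkS4class{CollectionField}.
#' @export
makeCollectionField <- function(geometry, radialDecayUm = 150, pixelUm = 10,
                                like = NULL, footprintRadiusUm = 0,
                                axialPadUm = 360, lateralHalfUm = 240) {
  stopifnot(is(geometry, "TaperGeometry"))
  .assertScalar(radialDecayUm, "radialDecayUm", positive = TRUE)
  if (!is.null(like)) {
    stopifnot(is(like, "IlluminationStack"))
    axialUm <- like@axialUm; lateralUm <- like@lateralUm
    pixelUm <- like@pixelUm
  } else {
    grid <- .taperGrid(geometry, pixelUm, axialPadUm, lateralHalfUm)
    axialUm <- grid$axialUm; lateralUm <- grid$lateralUm
  }
  prof <- exp(-abs(lateralUm) / radialDecayUm)
  vals <- matrix(prof, length(lateralUm), length(axialUm))
  mask <- matrix(abs(lateralUm) < footprintRadiusUm,
                 length(lateralUm), length(axialUm))
  vals[mask] <- 0
  new("CollectionField", values = vals, pixelUm = pixelUm,
      axialUm = axialUm, lateralUm = lateralUm, mask = mask)
}
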