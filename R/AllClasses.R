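# S4 containers for the depth-resolved photometry pipeline.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PlaqueField: 3-D plaque centroids with diameters
#'
#' Ground-truth point set standing in for tracer-labelled amyloid plaques.
#' Coordinates are micrometers in (AP, ML, DV) order, DV positive downward
#' with 0 at the brain surface.
#'
#' @slot points numeric matrix (n x 3), columns AP, ML, DV (um).
#' @slot diameters numeric vector of equivalent diameters (um), all > 0.
#' @slot genotype either \code{"affected"} or \code{"control"}.
#' @slot volumeUm 3 x 2 matrix of the bounding box (rows AP, ML, DV).
#' @slot meta list of generator parameters (density, seed, ...).
#' @exportClass PlaqueField
setClass("PlaqueField",
  representation(points = "matrix", diameters = "numeric",
                 genotype = "character", volumeUm = "matrix", meta = "list"))

setValidity("PlaqueField", function(object) {
  msg <- NULL
  p <- object@points
  if (ncol(p) != 3L) msg <- c(msg, "'points' must have 3 columns (AP, ML, DV)")
  if (nrow(p) != length(object@diameters))
    msg <- c(msg, "one diameter per point required")
  if (length(object@diameters) && any(object@diameters <= 0))
    msg <- c(msg, "all diameters must be > 0")
  if (length(p) && any(!is.finite(p)))
    msg <- c(msg, "coordinates must be finite")
  if (!object@genotype %in% c("affected", "control"))
    msg <- c(msg, "genotype must be 'affected' or 'control'")
  if (!identical(dim(object@volumeUm), c(3L, 2L)))
    msg <- c(msg, "'volumeUm' must be a 3 x 2 matrix")
  if (is.null(msg)) TRUE else msg
})

#' TaperGeometry: placement and optical extent of a tapered fiber
#'
#' @slot tip 3-D coordinate of the fiber tip (um, AP/ML/DV).
#' @slot axis unit direction of the fiber axis (pointing from tip toward
#'   the shallow end).
#' @slot emissionLengthUm optically active taper length (um).
#' @slot activeSpanUm axial interval swept by the galvo (um), at most the
#'   emission length. Default 1580 = 40 x 39.5.
#' @exportClass TaperGeometry
setClass("TaperGeometry",
  representation(tip = "numeric", axis = "numeric",
                 emissionLengthUm = "numeric", activeSpanUm = "numeric"))

setValidity("TaperGeometry", function(object) {
  msg <- NULL
  if (length(object@tip) != 3L) msg <- c(msg, "'tip' must be length 3")
  if (length(object@axis) != 3L) msg <- c(msg, "'axis' must be length 3")
  else if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "'axis' must have unit norm")
  if (object@activeSpanUm <= 0 ||
      object@activeSpanUm > object@emissionLengthUm + 1e-9)
    msg <- c(msg, "need 0 < activeSpanUm <= emissionLengthUm")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TaperGeometry-class
#' @param tip,axis,emissionLengthUm,activeSpanUm see slots.
#' @return a \code{TaperGeometry} object.
#' @export
#' @examples
#' TaperGeometry(tip = c(-3500, 2250, 3580))
TaperGeometry <- function(tip = c(0, 0, 3580), axis = c(0, 0, -1),
                          emissionLengthUm = 1800,
                          activeSpanUm = galvoSpanUm(41, 39.5)) {
  new("TaperGeometry", tip = as.numeric(tip),
      axis = as.numeric(axis) / sqrt(sum(axis^2)),
      emissionLengthUm = emissionLengthUm, activeSpanUm = activeSpanUm)
}

#' AcquisitionProtocol: pulse timing and scan structure
#'
#' Describes the time-division multiplexing of the light source: pulses of
#' \code{onMs} on / \code{offMs} off, repeated \code{reps} times per power
#' (flat fiber) or per galvo sweep (tapered fiber), across the listed
#' \code{powers}. The sample rate must place an integer number of samples
#' in each ON window.
#'
#' @slot onMs,offMs pulse timing (ms).
#' @slot baselineMs quiet gap separating power blocks (flat protocol, ms).
#' @slot reps pulses per power (flat) or sweeps per power per scan (TF).
#' @slot powers ordered light powers (flat: mW/mm2; TF: uW).
#' @slot sampleRateHz acquisition rate (Hz).
#' @slot galvoRangeV command-voltage range of the galvo sweep.
#' @slot scanIntervalS interval between successive scans (s; NA for flat).
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(onMs = "numeric", offMs = "numeric", baselineMs = "numeric",
                 reps = "numeric", powers = "numeric",
                 sampleRateHz = "numeric", galvoRangeV = "numeric",
                 scanIntervalS = "numeric"))

setValidity("AcquisitionProtocol", function(object) {
  msg <- NULL
  if (object@onMs <= 0 || object@offMs <= 0)
    msg <- c(msg, "onMs and offMs must be > 0")
  on <- object@sampleRateHz * object@onMs / 1000
  if (abs(on - round(on)) > 1e-9)
    msg <- c(msg, "sampleRateHz * onMs must give an integer sample count")
  if (length(object@galvoRangeV) != 2L)
    msg <- c(msg, "'galvoRangeV' must be length 2")
  if (length(object@powers) < 1L || any(object@powers <= 0))
    msg <- c(msg, "'powers' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Flat-fiber acquisition protocol
#'
#' 10 repetitions of 10 ms on / 5 ms off per light power, power blocks
#' separated by a 10-ms baseline, sampled at 5000 Hz.
#'
#' @param onMs,offMs,baselineMs,reps,powers,sampleRateHz protocol fields.
#' @return an \linkS4class{AcquisitionProtocol}.
#' @export
flatProtocol <- function(onMs = 10, offMs = 5, baselineMs = 10, reps = 10,
                         powers = c(0.1, 0.5, 1), sampleRateHz = 5000) {
  new("AcquisitionProtocol", onMs = onMs, offMs = offMs,
      baselineMs = baselineMs, reps = reps, powers = sort(powers),
      sampleRateHz = sampleRateHz, galvoRangeV = c(-1, 4.5),
      scanIntervalS = NA_real_)
}

#' Tapered-fiber acquisition protocol
#'
#' Laser cycles of 10 ms on / 5 ms off (67% duty) with the galvo swept from
#' -1 to 4.5 V in parallel with the ON periods; the sweep is repeated
#' \code{reps} times per power per scan, and scans recur every
#' \code{scanIntervalS} seconds.
#'
#' @param onMs,offMs,reps,powers,sampleRateHz,scanIntervalS protocol fields.
#' @return an \linkS4class{AcquisitionProtocol}.
#' @export
tfProtocol <- function(onMs = 10, offMs = 5, reps = 3,
                       powers = c(60, 100, 120, 140), sampleRateHz = 5000,
                       scanIntervalS = 300) {
  new("AcquisitionProtocol", onMs = onMs, offMs = offMs, baselineMs = 0,
      reps = reps, powers = sort(powers), sampleRateHz = sampleRateHz,
      galvoRangeV = c(-1, 4.5), scanIntervalS = scanIntervalS)
}

#' RawRecording: multiplexed photometry time series
#'
#' @slot t sample times (s), strictly increasing; gaps between scans are
#'   real gaps in time (acquisition is gated around scans).
#' @slot detector photodetector signal (a.u.).
#' @slot sync light-source on/off indicator (0/1).
#' @slot galvo galvo command voltage (V).
#' @slot meta list: protocol, level grid, ground truth, seed.
#' @exportClass RawRecording
setClass("RawRecording",
  representation(t = "numeric", detector = "numeric", sync = "numeric",
                 galvo = "numeric", meta = "list"))

setValidity("RawRecording", function(object) {
  msg <- NULL
  n <- length(object@t)
  if (length(object@detector) != n || length(object@sync) != n ||
      length(object@galvo) != n)
    msg <- c(msg, "t, detector, sync, galvo must have equal length")
  if (n && !all(object@sync %in% c(0, 1)))
    msg <- c(msg, "sync must be 0/1")
  prot <- object@meta$protocol
  if (!is.null(prot) && n) {
    rng <- prot@galvoRangeV
    g <- object@galvo[object@sync == 1]
    if (length(g) && (min(g) < rng[1] - 1e-9 || max(g) > rng[2] + 1e-9))
      msg <- c(msg, "galvo outside protocol range while sync = 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' SectionImage: a fluorescence section image with physical metadata
#'
#' Rows index DV (depth), columns index ML; the center of pixel
#' \code{[i, j]} sits at \code{origin + (c(i, j) - 0.5) * pixelUm}.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot pixelUm pixel size (um).
#' @slot apUm anterior-posterior coordinate of the section plane (um).
#' @slot thicknessUm section thickness (um).
#' @slot originUm coordinates (DV, ML) of the image corner (um).
#' @slot meta list (ground truth for synthetic images).
#' @exportClass SectionImage
setClass("SectionImage",
  representation(pixels = "matrix", pixelUm = "numeric", apUm = "numeric",
                 thicknessUm = "numeric", originUm = "numeric",
                 meta = "list"))

setValidity("SectionImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@pixelUm) || length(object@pixelUm) != 1L ||
      !is.finite(object@pixelUm) || object@pixelUm <= 0)
    msg <- c(msg, "'pixelUm' must be a positive scalar")
  if (length(object@originUm) != 2L)
    msg <- c(msg, "'originUm' must be length 2 (DV, ML)")
  if (is.null(msg)) TRUE else msg
})

#' FiberTrack: linear model of the fiber penetration track
#'
#' The track is the least-squares 3-D line through per-section annotations,
#' parameterized by depth (DV, um): lateral coordinates are affine in depth.
#' An axial shift of \code{s} um relabels depths so that the point reported
#' at depth \code{d} is the fitted point at \code{d + s} (the track is moved
#' up by \code{s}).
#'
#' @slot apCoef,mlCoef length-2 coefficients (intercept, slope vs depth).
#' @slot annotations the fitted input points (n x 3, AP/ML/DV um).
#' @slot hemisphere \code{"ipsi"} or \code{"contra"}.
#' @slot axialShiftUm applied axial shift (um, default 0).
#' @slot residualRmsUm root-mean-square lateral residual of the fit (um).
#' @exportClass FiberTrack
setClass("FiberTrack",
  representation(apCoef = "numeric", mlCoef = "numeric",
                 annotations = "matrix", hemisphere = "character",
                 axialShiftUm = "numeric", residualRmsUm = "numeric"))

setValidity("FiberTrack", function(object) {
  msg <- NULL
  if (length(object@apCoef) != 2L || length(object@mlCoef) != 2L)
    msg <- c(msg, "coefficients must be length 2 (intercept, slope)")
  if (!object@hemisphere %in% c("ipsi", "contra"))
    msg <- c(msg, "hemisphere must be 'ipsi' or 'contra'")
  if (is.null(msg)) TRUE else msg
})

#' DepthProfile: plaque counts and density along the track
#'
#' @slot depth depth grid (um).
#' @slot counts plaques within \code{radiusUm} of each track point.
#' @slot density counts per spherical volume (plaques per mm^3).
#' @slot radiusUm counting radius (um).
#' @slot meta list (tie-break noise seed, source, ...).
#' @exportClass DepthProfile
setClass("DepthProfile",
  representation(depth = "numeric", counts = "numeric", density = "numeric",
                 radiusUm = "numeric", meta = "list"))

setValidity("DepthProfile", function(object) {
  msg <- NULL
  n <- length(object@depth)
  if (length(object@counts) != n || length(object@density) != n)
    msg <- c(msg, "depth, counts, density must have equal length")
  if (is.null(msg)) TRUE else msg
})

#' ZProfile: z-scored fluorescence depth profile
#'
#' dF = (F - mean(F0)) / sd(F0) with F0 the fluorescence over the baseline
#' depth window.
#'
#' @slot depth depth grid (um).
#' @slot dF z-scored fluorescence.
#' @slot baselineWindowUm the baseline depth window (default c(0, 400)).
#' @slot meta list (filter window once smoothed, source, ...).
#' @exportClass ZProfile
setClass("ZProfile",
  representation(depth = "numeric", dF = "numeric",
                 baselineWindowUm = "numeric", meta = "list"))

setValidity("ZProfile", function(object) {
  msg <- NULL
  if (length(object@depth) != length(object@dF))
    msg <- c(msg, "depth and dF must have equal length")
  if (length(object@baselineWindowUm) != 2L)
    msg <- c(msg, "'baselineWindowUm' must be length 2")
  if (is.null(msg)) TRUE else msg
})

#' ProfileMatrix: per-sample z-scored depth profiles with labels
#'
#' Each row is one recording's depth profile, z-scored within the row
#' (mean 0, sample sd 1); 41 columns under the default depth grid.
#'
#' @slot values numeric matrix (samples x depths).
#' @slot labels factor with levels \code{control}, \code{affected}.
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
  representation(values = "matrix", labels = "factor"))

setValidity("ProfileMatrix", function(object) {
  msg <- NULL
  if (nrow(object@values) != length(object@labels))
    msg <- c(msg, "one label per row required")
  if (!all(levels(object@labels) %in% c("control", "affected")))
    msg <- c(msg, "labels must use levels 'control'/'affected'")
  if (nrow(object@values)) {
    m <- apply(object@values, 1, mean)
    s <- apply(object@values, 1, sd)
    if (max(abs(m)) > 1e-9 || max(abs(s - 1)) > 1e-9)
      msg <- c(msg, "rows must be z-scored (mean 0, sd 1)")
  }
  if (is.null(msg)) TRUE else msg
})

#' ConfusionMatrix: binary classification tallies
#'
#' Positive class is \code{affected}.
#'
#' @slot hits,misses,falseAlarms,correctRejections non-negative integers.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(hits = "integer", misses = "integer",
                 falseAlarms = "integer", correctRejections = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@hits, object@misses, object@falseAlarms,
         object@correctRejections)
  if (any(v < 0)) "all tallies must be >= 0" else TRUE
})

#' @rdname ConfusionMatrix-class
#' @param hits,misses,falseAlarms,correctRejections tallies.
#' @return a \code{ConfusionMatrix}.
#' @export
ConfusionMatrix <- function(hits, misses, falseAlarms, correctRejections) {
  new("ConfusionMatrix", hits = as.integer(hits), misses = as.integer(misses),
      falseAlarms = as.integer(falseAlarms),
      correctRejections = as.integer(correctRejections))
}

#' CollectionField: 2-D fiber collection-efficiency map C(x,y)
#'
#' Rows index the lateral (radial) coordinate, columns the axial coordinate
#' along the taper.
#'
#' @slot values non-negative matrix.
#' @slot pixelUm pixel size (um).
#' @slot axialUm axial coordinates of column centers (um).
#' @slot lateralUm lateral coordinates of row centers (um; 0 on the axis).
#' @slot mask logical matrix marking the fiber footprint (TRUE = inside).
#' @exportClass CollectionField
setClass("CollectionField",
  representation(values = "matrix", pixelUm = "numeric", axialUm = "numeric",
                 lateralUm = "numeric", mask = "matrix"))

setValidity("CollectionField", function(object) {
  msg <- NULL
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "C must be finite and >= 0")
  if (length(object@axialUm) != ncol(object@values) ||
      length(object@lateralUm) != nrow(object@values))
    msg <- c(msg, "axial/lateral coordinates must match the matrix")
  if (is.null(msg)) TRUE else msg
})

#' IlluminationStack: per-voltage illumination fields I(x,y,V)
#'
#' @slot values non-negative array (lateral x axial x voltage); after
#'   preprocessing the global maximum is 1.
#' @slot voltages galvo voltages, one per frame.
#' @slot pixelUm pixel size (um).
#' @slot axialUm,lateralUm pixel-center coordinates (um).
#' @slot meta list (generator truth: band centers, envelope, ...).
#' @exportClass IlluminationStack
setClass("IlluminationStack",
  representation(values = "array", voltages = "numeric", pixelUm = "numeric",
                 axialUm = "numeric", lateralUm = "numeric", meta = "list"))

setValidity("IlluminationStack", function(object) {
  msg <- NULL
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "'values' must be a 3-D array")
  else {
    if (d[3] != length(object@voltages))
      msg <- c(msg, "one voltage per frame required")
    if (length(object@axialUm) != d[2] || length(object@lateralUm) != d[1])
      msg <- c(msg, "axial/lateral coordinates must match the array")
  }
  if (any(object@values < 0)) msg <- c(msg, "I must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' PhotometryStack: photometry collection fields P = C x I
#'
#' Elementwise product of a collection field and an illumination stack;
#' inherits P >= 0 and (for normalized I <= 1) P <= C.
#'
#' @slot values array (lateral x axial x voltage).
#' @slot voltages galvo voltages.
#' @slot pixelUm pixel size (um).
#' @slot axialUm,lateralUm pixel-center coordinates (um).
#' @exportClass PhotometryStack
setClass("PhotometryStack",
  representation(values = "array", voltages = "numeric", pixelUm = "numeric",
                 axialUm = "numeric", lateralUm = "numeric"))

setValidity("PhotometryStack", function(object) {
  if (any(object@values < 0)) "P must be >= 0" else TRUE
})

#' AxialProfile: intensity or count profile along the fiber axis
#'
#' @slot positions axial positions (um), strictly monotone.
#' @slot values intensities (a.u.) or counts.
#' @slot kind one of \code{photometry}, \code{reference_count},
#'   \code{collection_count}.
#' @exportClass AxialProfile
setClass("AxialProfile",
  representation(positions = "numeric", values = "numeric",
                 kind = "character"))

setValidity("AxialProfile", function(object) {
  msg <- NULL
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "positions and values must have equal length")
  if (length(object@positions) > 1) {
    d <- diff(object@positions)
    if (!(all(d > 0) || all(d < 0)))
      msg <- c(msg, "positions must be strictly monotone")
  }
  if (!object@kind %in% c("photometry", "reference_count",
                          "collection_count"))
    msg <- c(msg, "unknown profile kind")
  if (is.null(msg)) TRUE else msg
})

#' @rdname AxialProfile-class
#' @param positions,values,kind see slots.
#' @return an \code{AxialProfile}.
#' @export
AxialProfile <- function(positions, values, kind = "photometry") {
  new("AxialProfile", positions = as.numeric(positions),
      values = as.numeric(values), kind = kind)
}

#' PowerCalibration: relative required power per galvo level
#'
#' PR(level) = (1/F) / min(1/F) for fluorescence F measured in a uniform
#' dye solution; PR >= 1 everywhere and min(PR) = 1 exactly.
#'
#' @slot levels galvo voltages.
#' @slot pr relative required power (dimensionless).
#' @exportClass PowerCalibration
setClass("PowerCalibration",
  representation(levels = "numeric", pr = "numeric"))

setValidity("PowerCalibration", function(object) {
  msg <- NULL
  if (length(object@levels) != length(object@pr))
    msg <- c(msg, "one PR value per level required")
  if (length(object@pr)) {
    if (min(object@pr) != 1) msg <- c(msg, "min(PR) must be exactly 1")
    if (any(object@pr < 1)) msg <- c(msg, "PR must be >= 1 everywhere")
  }
  if (is.null(msg)) TRUE else msg
})

#' GalvoScanMatrix: demodulated fluorescence per galvo level and time
#'
#' @slot levels galvo voltages of the analysis grid (within 0-4.5 V).
#' @slot times scan (or bin) times (s), strictly increasing.
#' @slot values fluorescence matrix (levels x times); NA marks level bins
#'   that received no samples.
#' @slot channel emission channel label (default \code{"440nm"}).
#' @slot powerUw laser power the matrix was demodulated at (uW).
#' @slot meta list (bin width, partial-bin flags, AF-subtraction note).
#' @exportClass GalvoScanMatrix
setClass("GalvoScanMatrix",
  representation(levels = "numeric", times = "numeric", values = "matrix",
                 channel = "character", powerUw = "numeric", meta = "list"))

setValidity("GalvoScanMatrix", function(object) {
  msg <- NULL
  if (nrow(object@values) != length(object@levels) ||
      ncol(object@values) != length(object@times))
    msg <- c(msg, "'values' must be levels x times")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' AFModel: per-level linear autofluorescence model
#'
#' AF(level, t) = a(level) * t + b(level), coefficients estimated on a
#' tracer-free (day 0) session by twofold cross-validation.
#'
#' @slot levels galvo voltages.
#' @slot slopes a (a.u. per second).
#' @slot intercepts b (a.u.).
#' @slot cvError mean held-out squared error per level.
#' @exportClass AFModel
setClass("AFModel",
  representation(levels = "numeric", slopes = "numeric",
                 intercepts = "numeric", cvError = "numeric"))

setValidity("AFModel", function(object) {
  msg <- NULL
  n <- length(object@levels)
  if (length(object@slopes) != n || length(object@intercepts) != n ||
      length(object@cvError) != n)
    msg <- c(msg, "one (a, b, cvError) triple per level required")
  if (length(object@cvError) && any(object@cvError < -1e-12, na.rm = TRUE))
    msg <- c(msg, "cvError must be >= 0")
  if (is.null(msg)) TRUE else msg
})
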