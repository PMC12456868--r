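# Ex vivo tapered-fiber computation: illumination-stack preprocessing,
# per-voltage illumination centroids, the photometry stack P = C x I,
# simulated photometry intensity profiles, and moving-ROI plaque counts.

#' Preprocess a raw illumination stack
#'
#' Per-frame background subtraction (the frame minimum, or a supplied
#' constant), negatives clipped to 0, then the whole stack divided by its
#' global maximum so \code{max(I) == 1}.
#'
#' @param stack an \linkS4class{IlluminationStack} or a 3-D array
#'   (lateral x axial x voltage).
#' @param voltages,pixelUm,axialUm,lateralUm grid metadata, required when a
#'   bare array is given.
#' @param background \code{"frame-min"} (default) or \code{"constant"}.
#' @param backgroundValue the constant to subtract when
#'   \code{background = "constant"}.
#' @return a normalized \linkS4class{IlluminationStack}.
#' @export
preprocessStack <- function(stack, voltages = NULL, pixelUm = NULL,
                            axialUm = NULL, lateralUm = NULL,
                            background = c("frame-min", "constant"),
                            backgroundValue = 0) {
  background <- match.arg(background)
  if (is(stack, "IlluminationStack")) {
    arr <- stack@values
    voltages <- stack@voltages; pixelUm <- stack@pixelUm
    axialUm <- stack@axialUm; lateralUm <- stack@lateralUm
    meta <- stack@meta
  } else {
    arr <- stack
    if (is.null(voltages) || is.null(pixelUm) ||
        is.null(axialUm) || is.null(lateralUm))
      stop("grid metadata required for a bare array")
    meta <- list()
  }
  if (!length(arr)) stop("empty stack")
  for (k in seq_len(dim(arr)[3])) {
    bg <- if (background == "frame-min") min(arr[, , k]) else backgroundValue
    arr[, , k] <- pmax(arr[, , k] - bg, 0)
  }
  m <- max(arr)
  if (m <= 0) stop("all-zero stack after background subtraction")
  meta$preprocessed <- TRUE
  new("IlluminationStack", values = arr / m, voltages = voltages,
      pixelUm = pixelUm, axialUm = axialUm, lateralUm = lateralUm,
      meta = meta)
}

#' Baseline frame from the terminal input angles
#'
#' Mean of the first and last voltage frames — the terminal input angles,
#' where a negligible amount of light is delivered into tissue.
#'
#' @param stack an \linkS4class{IlluminationStack}.
#' @return a matrix (lateral x axial).
#' @export
terminalBaseline <- function(stack) {
  stopifnot(is(stack, "IlluminationStack"))
  nV <- dim(stack@values)[3]
  (stack@values[, , 1] + stack@values[, , nV]) / 2
}

#' Axial centroid of an illumination frame
#'
#' Subtracts the terminal-angle baseline, clips at 0, projects the residual
#' intensity onto the fiber axis (column sums), and returns the
#' intensity-weighted mean axial coordinate. A frame indistinguishable from
#' the terminal angles (zero residual mass) raises a no-peak error.
#'
#' @param frame matrix (lateral x axial).
#' @param baseline matrix of the same shape (see
#'   \code{\link{terminalBaseline}}).
#' @param axialUm axial coordinates of the columns (um).
#' @return centroid axial position (um).
#' @export
illuminationCentroid <- function(frame, baseline, axialUm) {
  if (!identical(dim(frame), dim(baseline)))
    stop("frame and baseline must have the same shape")
  if (length(axialUm) != ncol(frame))
    stop("one axial coordinate per column required")
  resid <- pmax(frame - baseline, 0)
  w <- colSums(resid)
  tot <- sum(w)
  if (tot <= 0)
    stop("no peak: frame is indistinguishable from the terminal angles")
  sum(w * axialUm) / tot
}

#' Per-voltage illumination centroids of a stack
#'
#' Applies \code{\link{illuminationCentroid}} to every frame; frames that
#' raise a no-peak error yield NA with one warning.
#'
#' @param stack an \linkS4class{IlluminationStack}.
#' @param baseline baseline frame; default \code{\link{terminalBaseline}}.
#' @return numeric vector of axial positions (um), NA where no peak.
#' @export
stackCentroids <- function(stack, baseline = terminalBaseline(stack)) {
  stopifnot(is(stack, "IlluminationStack"))
  out <- vapply(seq_along(stack@voltages), function(k) {
    tryCatch(illuminationCentroid(stack@values[, , k], baseline,
                                  stack@axialUm),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(out))
    warning(sprintf("%d frame(s) had no illumination peak and were dropped",
                    sum(is.na(out))))
  out
}

#' Photometry stack P(x,y,V) = C(x,y) x I(x,y,V)
#'
#' Pixel-by-pixel product of the collection field with every illumination
#' frame. Grids must be aligned (same shape and pixel size). The result
#' inherits non-negativity, and for a normalized stack (I <= 1) satisfies
#' P <= C elementwise; both are asserted on construction.
#'
#' @param C a \linkS4class{CollectionField}.
#' @param I an \linkS4class{IlluminationStack}.
#' @return a \linkS4class{PhotometryStack}.
#' @export
photometryStack <- function(C, I) {
  stopifnot(is(C, "CollectionField"), is(I, "IlluminationStack"))
  dI <- dim(I@values)
  if (!identical(dim(C@values), dI[1:2]) ||
      abs(C@pixelUm - I@pixelUm) > 1e-9)
    stop("collection field and illumination stack grids are not aligned")
  P <- I@values * as.vector(C@values)   # recycles C over the voltage axis
  stopifnot(all(P >= 0))
  if (max(I@values) <= 1 + 1e-12)
    stopifnot(all(P <= as.vector(C@values) + 1e-12))
  new("PhotometryStack", values = P, voltages = I@voltages,
      pixelUm = I@pixelUm, axialUm = I@axialUm, lateralUm = I@lateralUm)
}

#' Simulated photometry intensity profile from a photometry stack
#'
#' The simulated photometry intensity at each voltage is the integral
#' (sum) of all pixels of P(,,V); each value is positioned at that
#' voltage's illumination centroid, and the profile is sorted by position.
#' Frames with NA centroids are dropped.
#'
#' @param P a \linkS4class{PhotometryStack}.
#' @param centroids per-voltage axial positions (um), e.g. from
#'   \code{\link{stackCentroids}}; NA drops the frame.
#' @return an \linkS4class{AxialProfile} of kind \code{photometry}.
#' @export
photometryProfile <- function(P, centroids) {
  stopifnot(is(P, "PhotometryStack"))
  if (length(centroids) != length(P@voltages))
    stop("one centroid per voltage required")
  keep <- which(!is.na(centroids))
  if (!length(keep)) stop("all frames were dropped: no centroids available")
  vals <- vapply(keep, function(k) sum(P@values[, , k]), numeric(1))
  ord <- order(centroids[keep])
  AxialProfile(positions = centroids[keep][ord], values = vals[ord],
               kind = "photometry")
}

#' Moving-ROI plaque count profile along the fiber axis
#'
#' Counts plaque centers inside a circular ROI of radius \code{radiusUm}
#' centered on the fiber axis and moved along it in steps of \code{stepUm}
#' (2-D, in the slice plane).
#'
#' @param points n x 2 matrix or data.frame of plaque centers,
#'   columns (axial um, lateral um) in fiber-aligned slice coordinates.
#' @param axialRangeUm range of ROI centers along the axis (um).
#' @param radiusUm ROI radius (um), > 0; default 250.
#' @param stepUm ROI step (um), > 0; default 40.
#' @param lateralCenterUm lateral coordinate of the axis (um), default 0.
#' @param kind profile kind label (\code{reference_count} or
#'   \code{collection_count}).
#' @return an \linkS4class{AxialProfile} of counts.
#' @export
roiCountProfile <- function(points, axialRangeUm, radiusUm = 250,
                            stepUm = 40, lateralCenterUm = 0,
                            kind = "reference_count") {
  .assertScalar(radiusUm, "radiusUm", positive = TRUE)
  .assertScalar(stepUm, "stepUm", positive = TRUE)
  .assertRange(axialRangeUm, "axialRangeUm")
  pts <- as.matrix(points)
  centers <- seq(axialRangeUm[1], axialRangeUm[2], by = stepUm)
  if (nrow(pts)) {
    lat2 <- (pts[, 2] - lateralCenterUm)^2
    cnt <- vapply(centers, function(a)
      sum((pts[, 1] - a)^2 + lat2 <= radiusUm^2 + 1e-9), numeric(1))
  } else cnt <- rep(0, length(centers))
  AxialProfile(positions = centers, values = cnt, kind = kind)
}

#' Compare a simulated photometry profile with a reference count profile
#'
#' The reference profile is rescaled by its maximum, matched to the
#' photometry positions by nearest step, and compared by Spearman rank
#' correlation (rank-based, so the rescaling does not affect rho; it is
#' applied for plotting comparability and reported in the result).
#'
#' @param photometry an \linkS4class{AxialProfile} (kind photometry).
#' @param reference an \linkS4class{AxialProfile} of plaque counts.
#' @return list with \code{rho}, \code{p.value}, \code{n}, \code{method},
#'   plus \code{matched}: the aligned (position, photometry, reference)
#'   table with the reference scaled to max 1.
#' @export
compareProfiles <- function(photometry, reference) {
  stopifnot(is(photometry, "AxialProfile"), is(reference, "AxialProfile"))
  refMax <- max(profileValues(reference))
  refScaled <- if (refMax > 0) profileValues(reference) / refMax
  else profileValues(reference)
  idx <- vapply(positions(photometry), function(p)
    which.min(abs(positions(reference) - p)), integer(1))
  res <- spearmanTest(profileValues(photometry), refScaled[idx])
  res$matched <- data.frame(position_um = positions(photometry),
                            photometry = profileValues(photometry),
                            reference = refScaled[idx])
  res
}
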