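# Histology: plaque detection in section images, fiber-track reconstruction,
# contralateral projection, and depth profiling along the track.

#' Detect plaque particles in a section image
#'
#' Background is estimated by grayscale morphological opening (a
#' rolling-ball equivalent) and subtracted; pixels above the
#' \code{thresholdQuantile} quantile of the background-subtracted image are
#' foreground; connected components are kept iff their equivalent diameter
#' \code{2 * sqrt(area / pi)} lies in \code{[minDUm, maxDUm]}. Because the
#' threshold is quantile-based, detection is invariant to rescaling the
#' image by any positive constant. An all-background image returns an
#' empty table (not an error).
#'
#' @param image a \linkS4class{SectionImage} (must carry a pixel size).
#' @param minDUm,maxDUm diameter filter bounds (um); defaults 11 and 20.
#' @param thresholdQuantile foreground quantile of the background-subtracted
#'   image (default 0.99). Not taken from any published protocol; override
#'   as needed.
#' @param backgroundRadiusUm radius of the opening structuring element (um).
#' @return data.frame with one row per particle: \code{ml_um, dv_um, ap_um,
#'   equiv_diameter_um, area_px}.
#' @export
detectPlaques <- function(image, minDUm = 11, maxDUm = 20,
                          thresholdQuantile = 0.99,
                          backgroundRadiusUm = 30) {
  stopifnot(is(image, "SectionImage"))
  px <- image@pixels
  pum <- image@pixelUm
  if (!is.finite(pum) || pum <= 0) stop("image has no valid pixel size")

  empty <- data.frame(ml_um = numeric(0), dv_um = numeric(0),
                      ap_um = numeric(0), equiv_diameter_um = numeric(0),
                      area_px = numeric(0))
  brushPx <- 2L * floor(backgroundRadiusUm / pum) + 1L
  if (brushPx >= 3L && min(dim(px)) > brushPx) {
    bg <- EBImage::opening(EBImage::Image(px),
                           EBImage::makeBrush(brushPx, shape = "disc"))
    sub <- px - EBImage::imageData(bg)
  } else sub <- px - min(px)
  thr <- quantile(sub, thresholdQuantile, names = FALSE)
  mask <- sub > thr
  if (!any(mask)) return(empty)

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nLab <- max(lab)
  if (nLab == 0) return(empty)
  area <- tabulate(lab[lab > 0], nbins = nLab)
  eqd <- 2 * sqrt(area / pi) * pum
  keep <- which(eqd >= minDUm & eqd <= maxDUm)
  if (!length(keep)) return(empty)

  idx <- which(lab > 0 & matrix(lab %in% keep, nrow(lab)))
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  g <- lab[idx]
  dv <- image@originUm[1] + (rows - 0.5) * pum
  ml <- image@originUm[2] + (cols - 0.5) * pum
  dvC <- tapply(dv, g, mean)
  mlC <- tapply(ml, g, mean)
  ord <- match(keep, as.integer(names(dvC)))
  data.frame(ml_um = as.numeric(mlC[ord]), dv_um = as.numeric(dvC[ord]),
             ap_um = image@apUm, equiv_diameter_um = eqd[keep],
             area_px = area[keep])
}

.asAnnotations <- function(annotations) {
  if (is.data.frame(annotations)) {
    need <- c("ap_um", "ml_um", "dv_um")
    if (!all(need %in% names(annotations)))
      stop("annotations need columns ap_um, ml_um, dv_um")
    annotations <- as.matrix(annotations[, need])
  }
  ann <- as.matrix(annotations)
  if (ncol(ann) != 3L) stop("annotations must be n x 3 (AP, ML, DV)")
  colnames(ann) <- c("AP", "ML", "DV")
  ann
}

#' Fit the fiber penetration track
#'
#' Least-squares 3-D line through per-section track annotations,
#' parameterized by depth (DV): the lateral coordinates AP and ML are each
#' regressed on DV. At least two annotated sections (with distinct depths)
#' are required.
#'
#' @param annotations n x 3 matrix or data.frame (\code{ap_um, ml_um,
#'   dv_um}) of annotated track coordinates (um).
#' @param hemisphere which hemisphere the annotations come from.
#' @return a \linkS4class{FiberTrack}; \code{residualRmsUm} is the RMS
#'   lateral residual of the fit.
#' @export
fitFiberTrack <- function(annotations, hemisphere = "ipsi") {
  ann <- .asAnnotations(annotations)
  if (nrow(ann) < 2L)
    stop("at least 2 annotated sections are required to fit a track")
  dv <- ann[, "DV"]
  if (diff(range(dv)) <= 0)
    stop("annotations must span more than one depth")
  fAp <- lm(ann[, "AP"] ~ dv)
  fMl <- lm(ann[, "ML"] ~ dv)
  res <- sqrt(mean(residuals(fAp)^2 + residuals(fMl)^2))
  new("FiberTrack", apCoef = unname(coef(fAp)), mlCoef = unname(coef(fMl)),
      annotations = ann, hemisphere = hemisphere, axialShiftUm = 0,
      residualRmsUm = res)
}

#' Point on the track at a given depth
#'
#' Evaluates the fitted line at depth \code{depthUm + axialShift(track)}:
#' a positive axial shift moves the whole track up, so the point reported
#' at a given depth takes the lateral course annotated that much deeper.
#'
#' @param track a \linkS4class{FiberTrack}.
#' @param depthUm depths (um); vectorized.
#' @return matrix (length(depthUm) x 3) of (AP, ML, DV) coordinates.
#' @export
trackPoint <- function(track, depthUm) {
  stopifnot(is(track, "FiberTrack"))
  d <- depthUm + track@axialShiftUm
  cbind(AP = track@apCoef[1] + track@apCoef[2] * d,
        ML = track@mlCoef[1] + track@mlCoef[2] * d,
        DV = depthUm)
}

#' Project the track onto the contralateral hemisphere
#'
#' Reflects the ML coordinate about the midline; AP and DV are unchanged
#' and the hemisphere flag flips. Mirroring twice is the identity, and
#' inter-point distances along the track are preserved.
#'
#' @param track a \linkS4class{FiberTrack}.
#' @param midlineMlUm ML coordinate of the midline (um); registered
#'   coordinates put it at 0.
#' @return the mirrored \linkS4class{FiberTrack}.
#' @export
mirrorTrack <- function(track, midlineMlUm = 0) {
  stopifnot(is(track, "FiberTrack"))
  ann <- track@annotations
  ann[, "ML"] <- 2 * midlineMlUm - ann[, "ML"]
  new("FiberTrack", apCoef = track@apCoef,
      mlCoef = c(2 * midlineMlUm - track@mlCoef[1], -track@mlCoef[2]),
      annotations = ann,
      hemisphere = if (track@hemisphere == "ipsi") "contra" else "ipsi",
      axialShiftUm = track@axialShiftUm,
      residualRmsUm = track@residualRmsUm)
}

#' Apply an axial (upward) shift to a track
#'
#' Used in the tapered-fiber analysis, where the penetration-track depth is
#' systematically overestimated and the track is shifted up 600 um before
#' profiling. Applied after any mirroring. \code{shiftTrack(t, 0)} removes
#' a previous shift.
#'
#' @param track a \linkS4class{FiberTrack}.
#' @param shiftUm upward shift (um); replaces any existing shift.
#' @return the shifted \linkS4class{FiberTrack}.
#' @export
shiftTrack <- function(track, shiftUm = 600) {
  stopifnot(is(track, "FiberTrack"))
  .assertScalar(shiftUm, "shiftUm")
  new("FiberTrack", apCoef = track@apCoef, mlCoef = track@mlCoef,
      annotations = track@annotations, hemisphere = track@hemisphere,
      axialShiftUm = shiftUm, residualRmsUm = track@residualRmsUm)
}

.asPoints3d <- function(plaques) {
  if (is(plaques, "PlaqueField")) return(plaquePoints(plaques))
  if (is.data.frame(plaques)) {
    need <- c("ap_um", "ml_um", "dv_um")
    if (!all(need %in% names(plaques)))
      stop("plaque table needs columns ap_um, ml_um, dv_um")
    m <- as.matrix(plaques[, need])
    colnames(m) <- c("AP", "ML", "DV")
    return(m)
  }
  m <- as.matrix(plaques)
  if (ncol(m) != 3L) stop("plaques must be n x 3 (AP, ML, DV)")
  colnames(m) <- c("AP", "ML", "DV")
  m
}

#' Plaque count and density depth profile along a track
#'
#' For each grid depth, counts the plaque centroids within \code{radiusUm}
#' of the track point at that depth (3-D Euclidean ball; the union of balls
#' along the track approximates a cylinder around it), and converts the
#' count to a density per spherical volume (plaques/mm^3). Counts every
#' 100-um step over 0-4000 um by default, i.e. 41 depths.
#'
#' @param plaques a \linkS4class{PlaqueField}, an n x 3 coordinate matrix,
#'   or a data.frame with \code{ap_um, ml_um, dv_um} (e.g. pooled
#'   \code{\link{detectPlaques}} output across sections).
#' @param track a \linkS4class{FiberTrack}.
#' @param radiusUm counting radius (um), > 0.
#' @param stepUm grid step (um), > 0.
#' @param depthRangeUm depth range (um).
#' @return a \linkS4class{DepthProfile}. Empty input gives all-zero counts.
#' @export
profileCounts <- function(plaques, track, radiusUm = 250, stepUm = 100,
                          depthRangeUm = c(0, 4000)) {
  .assertScalar(radiusUm, "radiusUm", positive = TRUE)
  .assertScalar(stepUm, "stepUm", positive = TRUE)
  pts <- .asPoints3d(plaques)
  grid <- seq(depthRangeUm[1], depthRangeUm[2], by = stepUm)
  centers <- trackPoint(track, grid)
  if (nrow(pts)) {
    d2 <- outer(rowSums(centers^2), rowSums(pts^2), "+") -
      2 * centers %*% t(pts)
    cnt <- rowSums(d2 <= radiusUm^2 + 1e-9)
  } else cnt <- rep(0, length(grid))
  volMm3 <- (4 / 3) * pi * (radiusUm / 1000)^3
  new("DepthProfile", depth = grid, counts = as.numeric(cnt),
      density = as.numeric(cnt) / volMm3, radiusUm = radiusUm,
      meta = list(stepUm = stepUm, hemisphere = track@hemisphere,
                  axialShiftUm = track@axialShiftUm))
}

#' Add rank tie-breaking noise to a depth profile
#'
#' Adds i.i.d. uniform(0, 1e-10) noise to each count so that rank-based
#' statistics are defined even when virtually no plaques are detected (the
#' control genotype); any two counts differing by >= 1 keep their order.
#' Density is recomputed from the noisy counts, preserving the
#' density-times-volume identity.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param seed integer seed (recorded in \code{meta$noiseSeed}).
#' @return the perturbed \linkS4class{DepthProfile}.
#' @export
addTiebreakNoise <- function(profile, seed = NULL) {
  stopifnot(is(profile, "DepthProfile"))
  eps <- withSeed(seed, runif(length(profile@depth), 0, 1e-10))
  volMm3 <- (4 / 3) * pi * (profile@radiusUm / 1000)^3
  cnt <- profile@counts + eps
  meta <- profile@meta
  meta$noiseSeed <- seed
  new("DepthProfile", depth = profile@depth, counts = cnt,
      density = cnt / volMm3, radiusUm = profile@radiusUm, meta = meta)
}

#' Read track annotations from CSV
#'
#' Expected columns: \code{section_ap_um, x_um, y_um} where x is ML and y
#' is DV in registered coordinates.
#'
#' @param path CSV path.
#' @return data.frame with \code{ap_um, ml_um, dv_um}.
#' @export
readTrackAnnotations <- function(path) {
  df <- read.csv(path)
  need <- c("section_ap_um", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("annotation CSV needs columns section_ap_um, x_um, y_um")
  data.frame(ap_um = df$section_ap_um, ml_um = df$x_um, dv_um = df$y_um)
}

#' Write / read a depth profile as CSV
#'
#' Columns: \code{depth_um, count, density_per_mm3}.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param path CSV path.
#' @param radiusUm counting radius to restore on read (um).
#' @return \code{path} (write) or a \linkS4class{DepthProfile} (read).
#' @export
writeDepthProfile <- function(profile, path) {
  stopifnot(is(profile, "DepthProfile"))
  write.csv(data.frame(depth_um = profile@depth, count = profile@counts,
                       density_per_mm3 = profile@density),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDepthProfile
#' @export
readDepthProfile <- function(path, radiusUm = 250) {
  df <- read.csv(path)
  new("DepthProfile", depth = df$depth_um, counts = df$count,
      density = df$density_per_mm3, radiusUm = radiusUm, meta = list())
}
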