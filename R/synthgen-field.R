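# Synthetic plaque fields and section images (ground truth generators).

#' Depth-dependent plaque density template
#'
#' A smooth density profile emulating the depth-varying amyloid burden seen
#' along a penetration that descends through cortex into the hippocampal
#' formation: a modest cortical baseline plus a broad deep peak (the
#' subiculum and surrounding regions carry dense pathology in the affected
#' genotype). Units are plaques per mm^3. The absolute scale is a free
#' generator parameter, not a literature-calibrated value.
#'
#' @param dvUm depth below the brain surface (um).
#' @param baseline cortical baseline density (plaques/mm^3).
#' @param peak additional density at the peak (plaques/mm^3).
#' @param peakDvUm peak depth (um).
#' @param widthUm Gaussian width of the peak (um).
#' @return density (plaques/mm^3) at each depth.
#' @export
#' @examples
#' curve(defaultPlaqueDensity(x), 0, 4000, xlab = "DV (um)")
defaultPlaqueDensity <- function(dvUm, baseline = 15, peak = 110,
                                 peakDvUm = 2800, widthUm = 500) {
  baseline + peak * exp(-0.5 * ((dvUm - peakDvUm) / widthUm)^2)
}

.defaultVolumeUm <- function() {
  rbind(AP = c(-4500, -2500), ML = c(500, 4500), DV = c(0, 4000))
}

.asVolume <- function(volumeUm) {
  v <- as.matrix(volumeUm)
  if (!identical(dim(v), c(3L, 2L)))
    stop("'volumeUm' must be a 3 x 2 matrix (rows AP, ML, DV)")
  if (any(!is.finite(v)) || any(v[, 2] <= v[, 1]))
    stop("'volumeUm' must be a nondegenerate box")
  rownames(v) <- c("AP", "ML", "DV")
  v
}

#' Generate a synthetic 3-D plaque field
#'
#' Draws plaque centroids from an inhomogeneous Poisson point process whose
#' intensity depends on depth (DV) only, by thinning a homogeneous process
#' at the maximum intensity. Diameters are i.i.d. uniform on
#' \code{diameterRangeUm}. For a fixed seed the draw is reproducible.
#'
#' @param densityPerMm3 either a single density (plaques/mm^3) or a
#'   function of depth (um) returning the local density. Must be
#'   non-negative everywhere; for \code{genotype = "control"} it defaults
#'   to 0 (no plaques).
#' @param volumeUm 3 x 2 matrix of box limits (um), rows AP, ML, DV.
#' @param seed integer seed (or NULL to use the current RNG stream).
#' @param diameterRangeUm range of equivalent diameters (um). The default
#'   11-20 um matches the detection filter, so geometry tests are not
#'   confounded by the size filter.
#' @param genotype \code{"affected"} or \code{"control"}.
#' @return a \linkS4class{PlaqueField}.
#' @export
#' @examples
#' pf <- makePlaqueField(defaultPlaqueDensity, seed = 7)
#' pf
makePlaqueField <- function(densityPerMm3, volumeUm = .defaultVolumeUm(),
                            seed = NULL, diameterRangeUm = c(11, 20),
                            genotype = c("affected", "control")) {
  genotype <- match.arg(genotype)
  if (missing(densityPerMm3)) {
    if (genotype == "control") densityPerMm3 <- 0
    else stop("'densityPerMm3' is required for an affected field")
  }
  vol <- .asVolume(volumeUm)
  .assertRange(diameterRangeUm, "diameterRangeUm")
  if (diameterRangeUm[1] <= 0) stop("diameters must be > 0")

  dens <- if (is.function(densityPerMm3)) densityPerMm3 else
    function(dv) rep_len(densityPerMm3, length(dv))
  dvGrid <- seq(vol["DV", 1], vol["DV", 2], length.out = 2048L)
  lam <- dens(dvGrid)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("density must be finite and >= 0 everywhere")
  lamMax <- max(lam)

  widths <- vol[, 2] - vol[, 1]
  volMm3 <- prod(widths) * 1e-9           # um^3 -> mm^3

  withSeed(seed, {
    nMax <- rpois(1L, lamMax * volMm3)
    pts <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("AP", "ML", "DV")))
    if (nMax > 0) {
      cand <- cbind(AP = runif(nMax, vol[1, 1], vol[1, 2]),
                    ML = runif(nMax, vol[2, 1], vol[2, 2]),
                    DV = runif(nMax, vol[3, 1], vol[3, 2]))
      keep <- runif(nMax) * lamMax <= dens(cand[, "DV"])
      pts <- cand[keep, , drop = FALSE]
    }
    d <- runif(nrow(pts), diameterRangeUm[1], diameterRangeUm[2])
    new("PlaqueField", points = pts, diameters = d, genotype = genotype,
        volumeUm = vol,
        meta = list(seed = seed, diameterRangeUm = diameterRangeUm,
                    lambdaMax = lamMax))
  })
}

#' Render a section image from a plaque field
#'
#' Plaques whose centroid falls inside the slab
#' \code{[apUm - thicknessUm/2, apUm + thicknessUm/2)} are drawn as filled
#' disks of their equivalent diameter (amplitude 1) at the section plane;
#' i.i.d. Gaussian background noise is added on top. An empty intersection
#' yields a valid all-background image. Pixel \code{[i, j]} is centered at
#' \code{origin + (c(i, j) - 0.5) * pixelUm} (rows DV, columns ML).
#'
#' @param field a \linkS4class{PlaqueField}.
#' @param apUm AP coordinate of the section plane (um).
#' @param thicknessUm section thickness (um).
#' @param pixelUm pixel size (um), > 0.
#' @param noiseSd standard deviation of the additive background noise.
#' @param seed integer seed for the noise (or NULL).
#' @param mlRangeUm,dvRangeUm image extent (um); default: the field's box.
#' @return a \linkS4class{SectionImage}; \code{meta$inSlab} records the
#'   ground-truth particles rendered (ML, DV, diameter).
#' @export
renderSectionImage <- function(field, apUm, thicknessUm = 100, pixelUm = 2,
                               noiseSd = 0, seed = NULL,
                               mlRangeUm = NULL, dvRangeUm = NULL) {
  stopifnot(is(field, "PlaqueField"))
  .assertScalar(pixelUm, "pixelUm", positive = TRUE)
  .assertScalar(thicknessUm, "thicknessUm", positive = TRUE)
  mlRangeUm <- mlRangeUm %||% field@volumeUm["ML", ]
  dvRangeUm <- dvRangeUm %||% field@volumeUm["DV", ]
  .assertRange(mlRangeUm, "mlRangeUm")
  .assertRange(dvRangeUm, "dvRangeUm")

  nr <- max(1L, ceiling(diff(dvRangeUm) / pixelUm))
  nc <- max(1L, ceiling(diff(mlRangeUm) / pixelUm))
  img <- matrix(0, nr, nc)
  dvC <- dvRangeUm[1] + (seq_len(nr) - 0.5) * pixelUm
  mlC <- mlRangeUm[1] + (seq_len(nc) - 0.5) * pixelUm

  pts <- field@points
  inSlab <- which(pts[, "AP"] >= apUm - thicknessUm / 2 &
                  pts[, "AP"] < apUm + thicknessUm / 2)
  for (k in inSlab) {
    mlc <- pts[k, "ML"]; dvc <- pts[k, "DV"]; r <- field@diameters[k] / 2
    ii <- which(abs(dvC - dvc) <= r)
    jj <- which(abs(mlC - mlc) <= r)
    if (!length(ii) || !length(jj)) next
    d2 <- outer((dvC[ii] - dvc)^2, (mlC[jj] - mlc)^2, "+")
    img[ii, jj][d2 <= r^2] <- 1
  }
  if (noiseSd > 0)
    img <- img + withSeed(seed, matrix(rnorm(nr * nc, 0, noiseSd), nr, nc))

  truth <- data.frame(ml_um = pts[inSlab, "ML"], dv_um = pts[inSlab, "DV"],
                      diameter_um = field@diameters[inSlab])
  new("SectionImage", pixels = img, pixelUm = pixelUm, apUm = apUm,
      thicknessUm = thicknessUm, originUm = c(dvRangeUm[1], mlRangeUm[1]),
      meta = list(inSlab = truth, noiseSd = noiseSd, seed = seed))
}

#' Write / read a section image as TIFF plus a JSON metadata sidecar
#'
#' The image is stored as 16-bit grayscale TIFF; the affine scale applied
#' for quantization, the pixel size, the AP coordinate, the thickness and
#' the image origin are stored in \code{<path>.json} so that
#' \code{readSectionImage} restores physical units.
#'
#' @param image a \linkS4class{SectionImage}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeSectionImage <- function(image, path) {
  stopifnot(is(image, "SectionImage"))
  px <- image@pixels
  lo <- min(px); hi <- max(px)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((px - lo) / scale, path, bits.per.sample = 16L)
  meta <- list(pixel_um = image@pixelUm, ap_um = image@apUm,
               thickness_um = image@thicknessUm,
               origin_um = image@originUm, offset = lo, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSectionImage
#' @export
readSectionImage <- function(path) {
  px <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("SectionImage", pixels = px * meta$scale + meta$offset,
      pixelUm = meta$pixel_um, apUm = meta$ap_um,
      thicknessUm = meta$thickness_um, originUm = as.numeric(meta$origin_um),
      meta = list())
}
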