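# Ex vivo photometry-stack computation.

test_that("stack preprocessing subtracts background and normalizes", {
  geom <- testGeometry()
  # two-frame stack with known values: hand-computed output
  arr <- array(0, c(2, 3, 2))
  arr[, , 1] <- matrix(c(1, 1, 1, 5, 1, 1), 2, 3)   # min 1, peak 5
  arr[, , 2] <- matrix(2, 2, 3)                     # constant frame
  st <- preprocessStack(arr, voltages = c(1, 2), pixelUm = 10,
                        axialUm = c(5, 15, 25), lateralUm = c(-5, 5))
  expect_equal(max(fieldValues(st)), 1)
  expect_equal(fieldValues(st)[, , 1],
               matrix(c(0, 0, 0, 1, 0, 0), 2, 3))
  # constant background frame becomes all-zero
  expect_true(all(fieldValues(st)[, , 2] == 0))

  # all-zero stack cannot be normalized
  expect_error(preprocessStack(array(3, c(2, 2, 2)), voltages = 1:2,
                               pixelUm = 1, axialUm = 1:2,
                               lateralUm = 1:2), "all-zero")

  # re-normalizing a generated stack keeps max at 1
  st2 <- preprocessStack(makeIlluminationStack(geom))
  expect_equal(max(fieldValues(st2)), 1)
})

test_that("illumination centroids are intensity-weighted axial means", {
  ax <- c(10, 20)
  # two-pixel axial profile (w1 at z1, w2 at z2) -> weighted mean
  frame <- matrix(c(3, 0, 1, 0), 2, 2)   # column sums 3 and 1
  base <- matrix(0, 2, 2)
  expect_equal(illuminationCentroid(frame, base, ax),
               (3 * 10 + 1 * 20) / 4)

  # frame equal to the terminal baseline -> no-peak error
  expect_error(illuminationCentroid(base, base, ax), "no peak")
  expect_error(illuminationCentroid(frame, frame, ax), "no peak")

  # symmetric Gaussian band centred at z0 -> centroid = z0 (half pixel)
  geom <- testGeometry()
  stack <- makeIlluminationStack(geom)
  k <- 15
  cen <- illuminationCentroid(fieldValues(stack)[, , k],
                              terminalBaseline(stack), axialCoords(stack))
  expect_lt(abs(cen - stack@meta$bandCentersUm[k]), pixelSize(stack) / 2)

  # shape mismatch is refused
  expect_error(illuminationCentroid(frame, matrix(0, 3, 2), ax), "shape")
})

test_that("the photometry stack is the elementwise product C x I", {
  geom <- testGeometry()
  I <- makeIlluminationStack(geom, seq(0.5, 4, length.out = 5))
  C <- makeCollectionField(geom, 150, like = I)

  # I == 1 -> P = C at every voltage
  I1 <- I
  I1@values[] <- 1
  P1 <- photometryStack(C, I1)
  for (k in 1:5) expect_equal(P1@values[, , k], fieldValues(C))

  # C == 0 -> P == 0
  C0 <- C
  C0@values[] <- 0
  expect_true(all(fieldValues(photometryStack(C0, I)) == 0))

  # random 8x8x3 stacks match a triple-loop oracle within 1e-12
  set.seed(9)
  Ir <- new("IlluminationStack",
            values = array(runif(8 * 8 * 3), c(8, 8, 3)), voltages = 1:3,
            pixelUm = 1, axialUm = 1:8, lateralUm = 1:8, meta = list())
  Cr <- new("CollectionField", values = matrix(runif(64), 8, 8), pixelUm = 1,
            axialUm = 1:8, lateralUm = 1:8,
            mask = matrix(FALSE, 8, 8))
  Pr <- photometryStack(Cr, Ir)
  oracle <- array(0, c(8, 8, 3))
  for (i in 1:8) for (j in 1:8) for (k in 1:3)
    oracle[i, j, k] <- Cr@values[i, j] * Ir@values[i, j, k]
  expect_lt(max(abs(fieldValues(Pr) - oracle)), 1e-12)

  # the bound P <= C holds elementwise
  expect_true(all(fieldValues(Pr) <= as.vector(Cr@values) + 1e-12))

  # misaligned grids are refused
  Cbad <- new("CollectionField", values = matrix(1, 4, 4), pixelUm = 1,
              axialUm = 1:4, lateralUm = 1:4, mask = matrix(FALSE, 4, 4))
  expect_error(photometryStack(Cbad, Ir), "not aligned")
})

test_that("photometry profiles integrate the stack at the centroids", {
  geom <- testGeometry()
  I <- makeIlluminationStack(geom)
  C <- makeCollectionField(geom, 150, like = I)
  P <- photometryStack(C, I)
  cens <- suppressWarnings(stackCentroids(I))
  prof <- suppressWarnings(photometryProfile(P, cens))

  # values are frame sums, sorted by centroid position
  keep <- which(!is.na(cens))
  expect_equal(profileValues(prof),
               vapply(keep[order(cens[keep])], function(k)
                 sum(P@values[, , k]), numeric(1)))
  expect_true(all(diff(positions(prof)) > 0))

  # P == 0 -> all intensities 0
  P0 <- P
  P0@values[] <- 0
  expect_true(all(profileValues(photometryProfile(P0, cens)) == 0))

  # single bright pixel: the integral is that pixel's value
  Ps <- P
  Ps@values[] <- 0
  Ps@values[3, 40, 10] <- 7.5
  ps <- photometryProfile(Ps, cens)
  expect_equal(profileValues(ps)[positions(ps) == cens[10]], 7.5)

  # linearity in C: profile(a * C) = a * profile(C)
  Ca <- C
  Ca@values <- 2.5 * C@values
  profA <- photometryProfile(photometryStack(Ca, I), cens)
  expect_equal(profileValues(profA), 2.5 * profileValues(prof),
               tolerance = 1e-9)

  # all frames dropped -> error
  expect_error(photometryProfile(P, rep(NA_real_, length(cens))),
               "all frames")
})

test_that("separable Gaussian C and I integrate to the analytic product", {
  # closed form: sum of exp(-x^2/2s^2) over a fine grid ~ sqrt(2*pi)*s/dx
  px <- 5
  ax <- seq(-300, 300, by = px) + px / 2
  lat <- seq(-200, 200, by = px) + px / 2
  sAx <- 40; sLatI <- 30; sLatC <- 60
  I <- new("IlluminationStack",
           values = array(outer(exp(-lat^2 / (2 * sLatI^2)),
                                exp(-ax^2 / (2 * sAx^2))),
                          c(length(lat), length(ax), 1)),
           voltages = 2, pixelUm = px, axialUm = ax, lateralUm = lat,
           meta = list())
  C <- new("CollectionField", values = matrix(exp(-lat^2 / (2 * sLatC^2)),
                                              length(lat), length(ax)),
           pixelUm = px, axialUm = ax, lateralUm = lat,
           mask = matrix(FALSE, length(lat), length(ax)))
  P <- photometryStack(C, I)
  sComb <- sqrt(1 / (1 / sLatI^2 + 1 / sLatC^2))
  analytic <- (sqrt(2 * pi) * sComb / px) * (sqrt(2 * pi) * sAx / px)
  expect_lt(abs(sum(P@values) - analytic) / analytic, 0.005)
})

test_that("moving-ROI counts agree with the brute-force oracle", {
  # membership: a plaque 200 um off-axis is counted at its step, one
  # 300 um off-axis never is
  pts <- rbind(c(520, 200), c(1000, 300))
  prof <- roiCountProfile(pts, c(0, 1580), radiusUm = 250, stepUm = 40)
  expect_equal(profileValues(prof)[positions(prof) == 520], 1)
  expect_equal(profileValues(prof)[positions(prof) == 1000], 0)
  # and not at steps more than the radius away along the axis
  expect_equal(profileValues(prof)[positions(prof) == 880], 0)

  # no plaques -> zeros
  expect_true(all(profileValues(
    roiCountProfile(matrix(numeric(0), 0, 2), c(0, 1580))) == 0))

  # 100 random 40-plaque fields vs the pairwise-distance oracle
  centers2d <- cbind(seq(0, 1580, by = 40), 0)
  for (s in 1:100) {
    set.seed(s)
    pts <- cbind(runif(40, -200, 1800), runif(40, -400, 400))
    prof <- roiCountProfile(pts, c(0, 1580))
    expect_equal(profileValues(prof),
                 bruteBallCounts(pts, centers2d, 250))
  }
})

test_that("profile comparison is scale-free and rank-based", {
  a <- AxialProfile(seq(0, 400, by = 40), c(1, 3, 2, 5, 4, 7, 6, 9, 8, 11, 10))
  expect_equal(compareProfiles(a, a)$rho, 1)

  # reference scaled by any positive constant -> rho unchanged
  b <- AxialProfile(positions(a), 13 * profileValues(a),
                    kind = "reference_count")
  expect_equal(compareProfiles(a, b)$rho, 1)
  res <- compareProfiles(a, b)
  expect_equal(max(res$matched$reference), 1)

  # nearest-step matching tolerates offset reference grids
  bOff <- AxialProfile(positions(a) + 15, profileValues(a),
                       kind = "reference_count")
  expect_equal(compareProfiles(a, bOff)$rho, 1)
})

test_that("the full ex vivo chain correlates with the slice density", {
  # a plaque field with an axial density ramp drives both the reference
  # ROI counts and the simulated photometry profile: the fiber-channel
  # image is the plaque brightness seen through the collection field,
  # and P = fiberImage x I integrates to the local plaque mass at each
  # illumination band. A plateau envelope keeps mid-sweep illumination
  # comparable across voltages (terminal angles still deliver nothing).
  geom <- testGeometry()
  plateau <- function(v, rng) pmin(1, 9 * illuminationEnvelope(v, rng))
  I <- makeIlluminationStack(geom, widthUm = 300, axialSigmaUm = 120,
                             envelope = plateau)
  C <- makeCollectionField(geom, 250, like = I)
  ax <- axialCoords(I); lat <- lateralCoords(I)

  rhoRef <- rhoTruth <- numeric(20)
  for (s in 1:20) {
    set.seed(400 + s)
    # plaque hotspot mid-taper over a uniform background
    nPl <- 200
    nB <- rbinom(1, nPl, 0.7)
    axPos <- pmin(pmax(c(rnorm(nB, 1100, 220),
                         runif(nPl - nB, 0, 1580)), 0), 1580)
    latPos <- runif(nPl, -220, 220)

    # reference image ROI counts along the fiber axis
    ref <- roiCountProfile(cbind(axPos, latPos), c(0, 1580))

    # fiber-channel image: Gaussian plaque blobs attenuated by C
    B <- matrix(0, length(lat), length(ax))
    for (p in seq_len(nPl))
      B <- B + outer(exp(-(lat - latPos[p])^2 / (2 * 15^2)),
                     exp(-(ax - axPos[p])^2 / (2 * 15^2)))
    fiberImg <- new("CollectionField", values = fieldValues(C) * B,
                    pixelUm = pixelSize(C), axialUm = ax, lateralUm = lat,
                    mask = C@mask)

    P <- photometryStack(fiberImg, I)
    cens <- suppressWarnings(stackCentroids(I))
    prof <- suppressWarnings(photometryProfile(P, cens))
    rhoRef[s] <- compareProfiles(prof, ref)$rho
    truthDens <- 0.7 * dnorm(positions(prof), 1100, 220) + 0.3 / 1580
    rhoTruth[s] <- spearmanTest(profileValues(prof), truthDens)$rho
  }
  expect_gte(median(rhoRef), 0.9)     # vs the reference-image ROI counts
  expect_gte(median(rhoTruth), 0.9)   # vs the generating density profile
})
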