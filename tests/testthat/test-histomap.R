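# Histology: particle detection, track reconstruction, depth profiling.

test_that("size filter keeps only particles between the diameter bounds", {
  box <- rbind(AP = c(-100, 100), ML = c(0, 900), DV = c(0, 300))
  f <- fixedPlaqueField(cbind(AP = c(0, 0, 0), ML = c(150, 450, 750),
                              DV = c(150, 150, 150)),
                        c(8, 15, 25), box)
  img <- renderSectionImage(f, apUm = 0, pixelUm = 2)
  det <- detectPlaques(img)   # 11-20 um bounds
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$ml_um - 450), 2)
  expect_lt(abs(det$equiv_diameter_um - 15), 4)
})

test_that("blank images yield zero particles, not an error", {
  img <- new("SectionImage", pixels = matrix(0, 50, 50), pixelUm = 2,
             apUm = 0, thicknessUm = 100, originUm = c(0, 0), meta = list())
  expect_identical(nrow(detectPlaques(img)), 0L)
  # constant background behaves the same
  img@pixels <- matrix(3.7, 50, 50)
  expect_identical(nrow(detectPlaques(img)), 0L)
})

test_that("detection recovers seeded particles within one pixel", {
  box <- rbind(AP = c(-100, 100), ML = c(0, 1200), DV = c(0, 1200))
  set.seed(5)
  n <- 8
  pts <- cbind(AP = rep(0, n),
               ML = seq(100, 1100, length.out = n),
               DV = 100 + (seq_len(n) %% 4) * 280)
  d <- runif(n, 12, 19)
  f <- fixedPlaqueField(pts, d, box)
  img <- renderSectionImage(f, apUm = 0, pixelUm = 2)
  det <- detectPlaques(img)
  expect_equal(nrow(det), n)
  ord <- order(det$ml_um)
  expect_lt(max(abs(det$ml_um[ord] - pts[, "ML"])), img@pixelUm)
  expect_lt(max(abs(det$dv_um[ord] - pts[, "DV"])), img@pixelUm)
})

test_that("quantile thresholding makes detection scale-invariant", {
  box <- rbind(AP = c(-100, 100), ML = c(0, 800), DV = c(0, 800))
  f <- fixedPlaqueField(cbind(AP = c(0, 0), ML = c(200, 600),
                              DV = c(250, 550)), c(14, 18), box)
  img <- renderSectionImage(f, apUm = 0, pixelUm = 2, noiseSd = 0.05,
                            seed = 11)
  base <- detectPlaques(img)
  for (k in c(0.01, 3, 1000)) {
    scaled <- img
    scaled@pixels <- img@pixels * k
    det <- detectPlaques(scaled)
    expect_identical(nrow(det), nrow(base))
    expect_equal(det$ml_um, base$ml_um)
  }
})

test_that("track fitting recovers a line through the annotations", {
  # perfectly collinear annotations: zero residual, exact recovery
  dv <- seq(0, 2000, by = 400)
  ann <- data.frame(ap_um = -3000 + 0.05 * dv, ml_um = 1500 - 0.02 * dv,
                    dv_um = dv)
  tr <- fitFiberTrack(ann)
  expect_lt(tr@residualRmsUm, 1e-9)
  p <- trackPoint(tr, c(0, 1000))
  expect_equal(p[1, ], c(AP = -3000, ML = 1500, DV = 0))
  expect_equal(p[2, ], c(AP = -2950, ML = 1480, DV = 1000))

  # a single annotation is underdetermined
  expect_error(fitFiberTrack(ann[1, ]), "at least 2")
})

test_that("noisy annotations keep the direction within 5 degrees", {
  # isotropic sd-20-um noise on 6 sections over a 2-mm span, 200 seeds
  dv <- seq(0, 2000, by = 400)
  trueDir <- c(0.05, -0.02, 1) / sqrt(sum(c(0.05, -0.02, 1)^2))
  ang <- vapply(1:200, function(s) {
    set.seed(s)
    ann <- data.frame(ap_um = -3000 + 0.05 * dv + rnorm(6, 0, 20),
                      ml_um = 1500 - 0.02 * dv + rnorm(6, 0, 20),
                      dv_um = dv)
    tr <- fitFiberTrack(ann)
    d <- c(tr@apCoef[2], tr@mlCoef[2], 1)
    d <- d / sqrt(sum(d^2))
    acos(pmin(1, sum(d * trueDir))) * 180 / pi
  }, numeric(1))
  expect_lt(max(ang), 5)
})

test_that("contralateral projection is a reflection about the midline", {
  dv <- c(0, 1000, 2000)
  tr <- fitFiberTrack(data.frame(ap_um = rep(-3000, 3),
                                 ml_um = 1500 + 0.1 * dv, dv_um = dv))
  m <- mirrorTrack(tr)
  expect_equal(unname(trackPoint(m, 0)[, "ML"]), -1500)
  expect_identical(hemisphere(m), "contra")

  # involution
  mm <- mirrorTrack(m)
  expect_equal(trackPoint(mm, c(0, 500, 2000)), trackPoint(tr, c(0, 500, 2000)))
  expect_identical(hemisphere(mm), "ipsi")

  # isometry along the track
  d0 <- dist(trackPoint(tr, c(0, 700, 1900)))
  d1 <- dist(trackPoint(m, c(0, 700, 1900)))
  expect_equal(as.numeric(d0), as.numeric(d1))

  # nonzero midline reflects about that ML
  m2 <- mirrorTrack(tr, midlineMlUm = 100)
  expect_equal(unname(trackPoint(m2, 0)[, "ML"]), 2 * 100 - 1500)
})

test_that("axial shift relabels depths and is removable", {
  dv <- c(0, 1000, 2000)
  tr <- fitFiberTrack(data.frame(ap_um = -3000 + 0.05 * dv,
                                 ml_um = 1500 - 0.02 * dv, dv_um = dv))
  sh <- shiftTrack(tr, 600)
  expect_equal(axialShift(sh), 600)
  # lateral course at depth d equals the unshifted course at d + 600
  expect_equal(trackPoint(sh, 400)[, c("AP", "ML")],
               trackPoint(tr, 1000)[, c("AP", "ML")])
  expect_equal(trackPoint(sh, 400)[, "DV"], c(DV = 400))
  # applying then removing the shift is the identity
  expect_equal(trackPoint(shiftTrack(sh, 0), c(0, 500)),
               trackPoint(tr, c(0, 500)))
})

test_that("depth profiles count within per-depth balls", {
  dv <- c(0, 2000)
  tr <- fitFiberTrack(data.frame(ap_um = c(-3000, -3000),
                                 ml_um = c(1500, 1500), dv_um = dv))

  # empty plaque list -> all-zero counts, valid profile
  none <- profileCounts(matrix(numeric(0), 0, 3), tr)
  expect_true(all(counts(none) == 0))
  expect_true(all(densities(none) == 0))

  # 0-4000 um at 100-um steps -> 41 grid points
  expect_identical(length(depths(none)), 41L)

  # ball membership at the stated radius
  pts <- rbind(c(-3000, 1500 + 200, 1000),    # 200 um from the d=1000 point
               c(-3000, 1500 + 300, 1000))    # 300 um away: outside
  pr <- profileCounts(pts, tr, radiusUm = 250)
  expect_identical(counts(pr)[depths(pr) == 1000], 1)

  # density times spherical volume equals the count exactly
  vol <- (4 / 3) * pi * (250 / 1000)^3
  expect_equal(densities(pr) * vol, counts(pr))
})

test_that("profile counts match the brute-force oracle on random fields", {
  dv <- c(0, 2000)
  tr <- fitFiberTrack(data.frame(ap_um = -3000 + 0.03 * dv,
                                 ml_um = 1500 - 0.05 * dv, dv_um = dv))
  grid <- depthGrid()
  centers <- trackPoint(tr, grid)
  for (s in 1:100) {
    set.seed(s)
    pts <- cbind(AP = runif(50, -3600, -2400), ML = runif(50, 900, 2100),
                 DV = runif(50, 0, 4000))
    pr <- profileCounts(pts, tr)
    expect_equal(counts(pr), bruteBallCounts(pts, centers, 250))
  }
})

test_that("counts are monotone in the radius and rigid-invariant", {
  dv <- c(0, 2000)
  tr <- fitFiberTrack(data.frame(ap_um = -3000 + 0.03 * dv,
                                 ml_um = 1500 - 0.05 * dv, dv_um = dv))
  set.seed(77)
  pts <- cbind(AP = runif(80, -3600, -2400), ML = runif(80, 900, 2100),
               DV = runif(80, 0, 4000))
  radii <- c(100, 250, 400, 800)
  tot <- vapply(radii, function(r)
    sum(counts(profileCounts(pts, tr, radiusUm = r))), numeric(1))
  expect_true(all(diff(tot) >= 0))

  # rigid transforms preserving the depth parameterization (rotation about
  # the DV axis plus in-plane translation) leave counts unchanged
  base <- counts(profileCounts(pts, tr))
  ann <- tr@annotations
  for (k in 1:20) {
    set.seed(k)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    sh <- runif(2, -500, 500)
    rot <- function(m) {
      xy <- m[, 1:2, drop = FALSE] %*% t(R)
      cbind(AP = xy[, 1] + sh[1], ML = xy[, 2] + sh[2], DV = m[, 3])
    }
    annR <- rot(ann)
    trR <- fitFiberTrack(data.frame(ap_um = annR[, 1], ml_um = annR[, 2],
                                    dv_um = annR[, 3]))
    expect_equal(counts(profileCounts(rot(pts), trR)), base)
  }
})

test_that("tie-break noise preserves ranks and breaks zero ties", {
  dv <- c(0, 2000)
  tr <- fitFiberTrack(data.frame(ap_um = c(-3000, -3000),
                                 ml_um = c(1500, 1500), dv_um = dv))
  wt <- profileCounts(matrix(numeric(0), 0, 3), tr)
  noisy <- addTiebreakNoise(wt, seed = 8)

  # all-zero control profile becomes strictly positive but tiny
  expect_true(all(counts(noisy) > 0))
  expect_true(all(counts(noisy) < 1e-10))

  # counts differing by >= 1 keep their order
  p2 <- new("DepthProfile", depth = c(0, 100), counts = c(0, 5),
            density = c(0, 5), radiusUm = 250, meta = list())
  n2 <- addTiebreakNoise(p2, seed = 1)
  expect_true(counts(n2)[1] < counts(n2)[2])

  # deterministic for a fixed seed; density identity maintained
  expect_identical(counts(addTiebreakNoise(wt, seed = 8)), counts(noisy))
  vol <- (4 / 3) * pi * (250 / 1000)^3
  expect_equal(densities(noisy) * vol, counts(noisy))
})

test_that("render -> detect -> profile recovers ground-truth counts", {
  # well-separated in-range plaques in one slab, noiseless: the full
  # histology chain returns the exact generator count
  box <- rbind(AP = c(-100, 100), ML = c(0, 1600), DV = c(0, 1600))
  pts <- as.matrix(expand.grid(ML = seq(200, 1400, by = 300),
                               DV = seq(200, 1400, by = 300)))
  pts <- cbind(AP = 0, pts)[, c("AP", "ML", "DV")]
  f <- fixedPlaqueField(pts, rep(15, nrow(pts)), box)
  img <- renderSectionImage(f, apUm = 0, pixelUm = 2)
  det <- detectPlaques(img)
  expect_identical(nrow(det), nrow(pts))

  dvs <- c(0, 1600)
  tr <- fitFiberTrack(data.frame(ap_um = c(0, 0), ml_um = c(800, 800),
                                 dv_um = dvs))
  pr <- profileCounts(det, tr, radiusUm = 250, stepUm = 100,
                      depthRangeUm = c(0, 1600))
  centers <- trackPoint(tr, depths(pr))
  expect_equal(counts(pr), bruteBallCounts(pts, centers, 250))
})

test_that("annotation and profile CSV round trips work", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(section_ap_um = c(-3000, -3100),
                       x_um = c(1500, 1520), y_um = c(100, 600)),
            path, row.names = FALSE)
  ann <- readTrackAnnotations(path)
  expect_named(ann, c("ap_um", "ml_um", "dv_um"))
  unlink(path)

  pr <- new("DepthProfile", depth = c(0, 100), counts = c(1, 2),
            density = c(1, 2) / ((4 / 3) * pi * 0.25^3), radiusUm = 250,
            meta = list())
  p2 <- tempfile(fileext = ".csv")
  writeDepthProfile(pr, p2)
  back <- readDepthProfile(p2)
  expect_equal(counts(back), counts(pr))
  expect_equal(densities(back), densities(pr))
  unlink(p2)
})
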