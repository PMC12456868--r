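# In vivo tapered-fiber analysis.

test_that("power calibration follows PR = (1/F) / min(1/F)", {
  # hand evaluation: F = [2, 1, 4] -> PR = [2, 4, 1]
  expect_equal(prValues(calibratePower(c(2, 1, 4))), c(2, 4, 1))

  # uniform F -> PR == 1 everywhere; min(PR) is exactly 1
  expect_equal(prValues(calibratePower(rep(3, 5))), rep(1, 5))
  pr <- prValues(calibratePower(runif(41, 0.5, 2)))
  expect_identical(min(pr), 1)
  expect_true(all(pr >= 1))

  # scale invariance
  F <- c(1.2, 0.7, 2.5, 1.9)
  expect_equal(prValues(calibratePower(F)),
               prValues(calibratePower(17 * F)))

  # nonpositive fluorescence is refused
  expect_error(calibratePower(c(1, 0, 2)), "> 0")
})

test_that("applying PR to the dye forward model equalizes fluorescence", {
  lv <- seq(0, 4.5, length.out = 41)
  prot <- tfProtocol(reps = 5, powers = c(60, 80), scanIntervalS = 60)

  # measure once at uniform power, calibrate, re-measure with PR applied
  rec0 <- simulateDyeCalibration(prot, levels = lv)
  F0 <- rowMeans(scanValues(demodulateScan(rec0, prot, lv)))
  cal <- calibratePower(F0, lv)
  rec1 <- simulateDyeCalibration(prot, levels = lv,
                                 levelPowerScale = prValues(cal))
  F1 <- rowMeans(scanValues(demodulateScan(rec1, prot, lv)))
  expect_lt(diff(range(F1)) / mean(F1), 0.01)

  # the loop also closes under measurement noise
  recN <- simulateDyeCalibration(prot, levels = lv, noiseSd = 0.002,
                                 seed = 31)
  calN <- calibratePower(rowMeans(scanValues(
    demodulateScan(recN, prot, lv))), lv)
  recN1 <- simulateDyeCalibration(prot, levels = lv, noiseSd = 0.002,
                                  levelPowerScale = prValues(calN),
                                  seed = 32)
  FN1 <- rowMeans(scanValues(demodulateScan(recN1, prot, lv)))
  expect_lt(diff(range(FN1)) / mean(FN1), 0.01)
})

test_that("scan demodulation inverts the generator exactly", {
  lv <- seq(0, 4.5, length.out = 41)
  expect_equal(diff(lv)[1], 0.1125)   # 41 levels over 0-4.5 V

  prot <- testTfProtocol(scanIntervalS = 60)
  dens <- defaultPlaqueDensity(galvoAxialUm(lv, testGeometry()))
  rec <- simulateRecording(dens, prot, durationS = 300,
                           injectionTimeS = 120, riseTauS = 60,
                           afSlope = -3e-5, afIntercept = 1.1, gain = 0.004,
                           levels = lv)
  m <- demodulateScan(rec, prot, lv)
  truth <- expectedScanMatrix(rec)
  expect_lt(max(abs(scanValues(m) - scanValues(truth))), 1e-9)
  expect_equal(scanTimes(m), scanTimes(truth))
  expect_true(all(scanLevels(m) == lv))

  # four-power protocol: the analysis default picks 120 uW
  prot4 <- tfProtocol(scanIntervalS = 60)
  lv9 <- seq(0, 4.5, length.out = 9)
  rec4 <- simulateRecording(30, prot4, durationS = 60, levels = lv9)
  m4 <- demodulateScan(rec4, prot4, lv9)
  expect_identical(m4@powerUw, 120)
  expect_lt(max(abs(scanValues(m4) -
                      scanValues(expectedScanMatrix(rec4, 120)))), 1e-9)
  # selecting another power rescales linearly
  m60 <- demodulateScan(rec4, prot4, lv9, powerSelect = 60)
  expect_equal(scanValues(m60), scanValues(m4) * 60 / 120, tolerance = 1e-9)
})

test_that("autofluorescence fitting recovers the per-level line", {
  lv <- seq(0, 4.5, length.out = 5)
  times <- seq(0, 3000, by = 300)
  a <- c(-2e-5, 1e-5, 0, 5e-5, -4e-5)
  b <- c(1, 1.2, 0.9, 1.05, 1.3)
  vals <- outer(a, times) + b
  gsm <- new("GalvoScanMatrix", levels = lv, times = times, values = vals,
             channel = "440nm", powerUw = 120, meta = list())

  # exact line, noiseless: coefficients within 1e-9, cv error ~ 0
  af <- fitAutofluorescence(gsm)
  expect_lt(max(abs(afSlopes(af) - a)), 1e-9)
  expect_lt(max(abs(afIntercepts(af) - b)), 1e-9)
  expect_lt(max(cvError(af)), 1e-12)

  # constant F = c -> a = 0, b = c
  gsmC <- new("GalvoScanMatrix", levels = lv, times = times,
              values = matrix(2.5, 5, length(times)), channel = "440nm",
              powerUw = 120, meta = list())
  afC <- fitAutofluorescence(gsmC)
  expect_lt(max(abs(afSlopes(afC))), 1e-12)
  expect_equal(afIntercepts(afC), rep(2.5, 5))

  # too few timepoints per level
  short <- new("GalvoScanMatrix", levels = lv, times = times[1:3],
               values = vals[, 1:3], channel = "440nm", powerUw = 120,
               meta = list())
  expect_error(fitAutofluorescence(short), "fewer than 4")
})

test_that("noisy AF slopes land within OLS sampling theory bounds", {
  times <- seq(0, 6000, by = 300)
  aTrue <- 3e-5; bTrue <- 1; sig <- 0.01
  # theoretical SE of the OLS slope on one fold (11 interleaved points);
  # the averaged two-fold estimate is at least as precise
  seFold <- function(t) sig / sqrt(sum((t - mean(t))^2))
  # the two folds are independent, so the averaged slope has SE
  # sqrt(se1^2 + se2^2) / 2
  seAvg <- sqrt(seFold(times[c(TRUE, FALSE)])^2 +
                  seFold(times[c(FALSE, TRUE)])^2) / 2
  ok <- vapply(1:200, function(s) {
    set.seed(s)
    y <- aTrue * times + bTrue + rnorm(length(times), 0, sig)
    gsm <- new("GalvoScanMatrix", levels = 0, times = times,
               values = matrix(y, 1), channel = "440nm", powerUw = 120,
               meta = list())
    abs(afSlopes(fitAutofluorescence(gsm)) - aTrue) <= 3 * seAvg
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("AF subtraction removes the modelled baseline", {
  lv <- seq(0, 4.5, length.out = 5)
  times <- seq(0, 3000, by = 300)
  a <- seq(-3e-5, 3e-5, length.out = 5)
  b <- seq(0.9, 1.3, length.out = 5)
  af <- new("AFModel", levels = lv, slopes = a, intercepts = b,
            cvError = rep(0, 5))

  # day 1 generated exactly from the model -> Fm == 0
  day1 <- new("GalvoScanMatrix", levels = lv, times = times,
              values = outer(a, times) + b, channel = "440nm",
              powerUw = 120, meta = list())
  fm <- subtractAf(day1, af)
  expect_lt(max(abs(scanValues(fm))), 1e-9)

  # day 1 = AF + known tracer term -> Fm = tracer term (linearity)
  tracer <- outer(seq(0, 0.4, length.out = 5),
                  1 - exp(-pmax(times - 600, 0) / 900))
  day1b <- day1
  day1b@values <- day1@values + tracer
  expect_lt(max(abs(scanValues(subtractAf(day1b, af)) - tracer)), 1e-9)

  # level-grid mismatch is refused
  afBad <- new("AFModel", levels = lv + 0.1, slopes = a, intercepts = b,
               cvError = rep(0, 5))
  expect_error(subtractAf(day1, afBad), "do not match")
})

test_that("time binning averages within 5-min bins", {
  lv <- c(0, 1)
  # 30 min at 1-min sampling -> 6 five-minute bins
  times <- seq(0, 29 * 60, by = 60)
  vals <- rbind(rep(2, 30), seq_along(times))  # constant and a ramp
  gsm <- new("GalvoScanMatrix", levels = lv, times = times, values = vals,
             channel = "440nm", powerUw = 120, meta = list())
  binned <- binTimecourse(gsm, 300)
  expect_identical(ncol(scanValues(binned)), 6L)

  # constant signal -> constant bins
  expect_true(all(scanValues(binned)[1, ] == 2))

  # linear ramp -> bin means equal the ramp at the bin timestamps
  ramp <- function(t) 1 + t / 60
  expect_lt(max(abs(scanValues(binned)[2, ] - ramp(scanTimes(binned)))),
            1e-9)

  # trailing partial bin is kept and flagged
  gsm2 <- new("GalvoScanMatrix", levels = lv, times = times[1:27],
              values = vals[, 1:27], channel = "440nm", powerUw = 120,
              meta = list())
  b2 <- binTimecourse(gsm2, 300)
  expect_identical(ncol(scanValues(b2)), 6L)
  expect_true(b2@meta$partialTrailing)
})

test_that("extrema depths take the window median with low-index ties", {
  lv <- seq(0, 4.5, length.out = 4)
  times <- seq(0, 14700, by = 300)
  set.seed(12)

  # level 3 given the largest plateau -> maxLevel = 3
  vals <- matrix(rnorm(4 * length(times), 0, 0.01), 4)
  vals[3, ] <- vals[3, ] + 1
  vals[2, ] <- vals[2, ] - 1
  gsm <- new("GalvoScanMatrix", levels = lv, times = times, values = vals,
             channel = "440nm", powerUw = 120, meta = list())
  ext <- extremaDepths(gsm, c(30, 240))
  expect_identical(ext$maxLevel, 3L)
  expect_identical(ext$minLevel, 2L)

  # all levels identical -> ties break to the lowest index
  gsmT <- new("GalvoScanMatrix", levels = lv, times = times,
              values = matrix(1, 4, length(times)), channel = "440nm",
              powerUw = 120, meta = list())
  extT <- extremaDepths(gsmT, c(30, 240))
  expect_identical(extT$maxLevel, 1L)
  expect_identical(extT$minLevel, 1L)

  # brute-force median scan over random matrices
  for (s in 1:100) {
    set.seed(600 + s)
    v <- matrix(rnorm(4 * length(times)), 4)
    g <- new("GalvoScanMatrix", levels = lv, times = times, values = v,
             channel = "440nm", powerUw = 120, meta = list())
    e <- extremaDepths(g, c(30, 240))
    sel <- times >= 30 * 60 & times <= 240 * 60
    med <- apply(v[, sel], 1, median)
    expect_identical(e$maxLevel, which.max(med))
    expect_identical(e$minLevel, which.min(med))
  }

  # empty window is an error
  expect_error(extremaDepths(gsm, c(500, 600)), "window")
})

test_that("trace z-scoring uses the first-25-min baseline", {
  lv <- 0
  times <- seq(150, by = 300, length.out = 10)   # bin timestamps
  x <- c(1, 1.2, 0.8, 1.1, 0.9, 3, 4, 5, 5, 5)
  gsm <- new("GalvoScanMatrix", levels = lv, times = times,
             values = matrix(x, 1), channel = "440nm", powerUw = 120,
             meta = list())

  # hand-worked: baseline = first 5 bins (times < 1500 s)
  b <- x[1:5]
  expected <- (x - mean(b)) / sd(b)
  dF <- zscoreTrace(gsm, 1, smoothWindow = 1L)
  expect_equal(as.numeric(dF), expected)

  # affine invariance of the standardized trace
  gsm2 <- gsm
  gsm2@values <- matrix(2 * x + 7, 1)
  expect_equal(as.numeric(zscoreTrace(gsm2, 1, smoothWindow = 1L)),
               expected)

  # smoothing applies the moving median after z-scoring
  expect_equal(as.numeric(zscoreTrace(gsm, 1, smoothWindow = 3L)),
               movingMedian(expected, 3))

  # degenerate baseline errors
  gsmC <- gsm
  gsmC@values <- matrix(rep(1, 10), 1)
  expect_error(zscoreTrace(gsmC, 1), "degenerate")
})

test_that("late-window depth profiles average the stated bins", {
  lv <- seq(0, 4.5, length.out = 41)
  geom <- testGeometry()
  times <- seq(150, by = 300, length.out = 49)
  prof0 <- defaultPlaqueDensity(galvoAxialUm(lv, geom)) / 100
  vals <- matrix(prof0, 41, 49)   # constant in time
  gsm <- new("GalvoScanMatrix", levels = lv, times = times, values = vals,
             channel = "440nm", powerUw = 120, meta = list())

  # constant-in-time Fm: the window profile equals any single bin
  ap <- depthProfileWindow(gsm, c(210, 240), geom)
  expect_equal(profileValues(ap), prof0[order(galvoAxialUm(lv, geom))])
  expect_true(all(diff(positions(ap)) > 0))

  # window outside the recording errors
  expect_error(depthProfileWindow(gsm, c(400, 500), geom), "window")
})

test_that("the paired signed-rank test matches exact enumeration", {
  # identical pairs -> degenerate: statistic 0, p = 1, with a warning
  expect_warning(res <- pairedExtremaTest(1:6, 1:6), "zero")
  expect_identical(res$p.value, 1)
  expect_identical(res$statistic, 0)

  # 8 pairs all shifted +1 -> exact two-sided p = 2 / 2^8
  res8 <- pairedExtremaTest(2:9, 1:8)
  expect_equal(res8$p.value, 2 / 256)
  expect_equal(res8$statistic, 36)

  # agreement with stats::wilcox.test exact p on untied data
  for (s in 1:25) {
    set.seed(s)
    a <- rnorm(9); b <- rnorm(9)
    ours <- pairedExtremaTest(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }

  # null calibration under random signs: the exact p is valid
  # (super-uniform, P(p <= a) <= a) at every level; the statistic is
  # discrete so plain KS uniformity does not apply
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    d <- sample(c(-1, 1), 10, replace = TRUE) * runif(10, 0.5, 2)
    pairedExtremaTest(d, rep(0, 10))$p.value
  }, numeric(1))
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(a * (1 - a) / 500)
    expect_lte(mean(ps <= a), a + 3 * se)
  }
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.65)
})
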