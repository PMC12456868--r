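# End-to-end study orchestration: synthetic cohorts through the flat-fiber
# and tapered-fiber pipelines, classification, and group statistics.

#' Default study configuration
#'
#' All tunables of \code{\link{runStudy}} in one serializable list:
#' cohort sizes, generator noise, acquisition structure and analysis
#' windows. The defaults run a small demonstration cohort; the full study
#' conditions (20+20 flat animals, 12+7 tapered-fiber recordings) are set
#' by the corresponding arguments.
#'
#' @param seed master seed for every stage.
#' @param nAffectedFlat,nControlFlat flat-fiber cohort sizes.
#' @param nAffectedTf,nControlTf tapered-fiber cohort sizes.
#' @param flatNoiseSd,tfNoiseSd detector noise sd per sample (a.u.).
#' @param tfDurationS tapered-fiber session length (s); must cover the
#'   210-240 min profile window.
#' @param tfInjectionS tracer injection time on day 1 (s).
#' @param riseTauS tracer rise time constant (s).
#' @param gain plateau fluorescence per unit plaque density.
#' @param gainSdLog per-animal lognormal spread of pathology load.
#' @return a named list.
#' @export
studyConfig <- function(seed = 1, nAffectedFlat = 4, nControlFlat = 4,
                        nAffectedTf = 3, nControlTf = 2,
                        flatNoiseSd = 0.05, tfNoiseSd = 0.05,
                        tfDurationS = 14700, tfInjectionS = 1800,
                        riseTauS = 1800, gain = 0.004, gainSdLog = 0.3) {
  list(seed = seed, nAffectedFlat = nAffectedFlat,
       nControlFlat = nControlFlat, nAffectedTf = nAffectedTf,
       nControlTf = nControlTf, flatNoiseSd = flatNoiseSd,
       tfNoiseSd = tfNoiseSd, tfDurationS = tfDurationS,
       tfInjectionS = tfInjectionS, riseTauS = riseTauS, gain = gain,
       gainSdLog = gainSdLog)
}

# ground-truth density profile as a DepthProfile with rank tie-break noise,
# so rank statistics are defined for plaque-free controls
.truthProfile <- function(densities, depthsUm, radiusUm = 250) {
  volMm3 <- (4 / 3) * pi * (radiusUm / 1000)^3
  prof <- new("DepthProfile", depth = depthsUm,
              counts = densities * volMm3, density = densities,
              radiusUm = radiusUm, meta = list(source = "generator truth"))
  addTiebreakNoise(prof, seed = NULL)
}

#' Run a synthetic flat-fiber cohort through the acute pipeline
#'
#' For each animal: draw a depth-density profile (affected: the density
#' template scaled by a per-animal lognormal gain; control: no plaques),
#' simulate the depth-sweep recordings, demodulate, z-score against the
#' 0-400 um baseline, median-smooth (window 4), and correlate the profile
#' with the ground-truth density by Spearman's rho (controls carry
#' tie-break noise on their all-zero truth, mirroring the histological
#' quantification).
#'
#' @param nAffected,nControl cohort sizes.
#' @param noiseSd detector noise sd per sample.
#' @param seed integer seed.
#' @param protocol flat-fiber \linkS4class{AcquisitionProtocol}.
#' @param template density template (function of depth, plaques/mm^3).
#' @param gain,gainSdLog fluorescence gain and per-animal spread.
#' @param depthsUm depth grid.
#' @return list with \code{rho} (data.frame animal/genotype/rho/p),
#'   \code{profiles} (unsmoothed \linkS4class{ZProfile}s for
#'   classification) and \code{labels}.
#' @export
flatCohortStudy <- function(nAffected, nControl, noiseSd = 0.05, seed = 1,
                            protocol = flatProtocol(),
                            template = defaultPlaqueDensity, gain = 0.004,
                            gainSdLog = 0.3, depthsUm = depthGrid()) {
  genos <- rep(c("affected", "control"), c(nAffected, nControl))
  if (!length(genos)) stop("cohort must contain at least one animal")
  withSeed(seed, {
    profiles <- vector("list", length(genos))
    rows <- vector("list", length(genos))
    for (i in seq_along(genos)) {
      g <- exp(rnorm(1, 0, gainSdLog))
      dens <- if (genos[i] == "affected") g * template(depthsUm)
      else rep(0, length(depthsUm))
      ses <- simulateFlatSession(dens, depthsUm, protocol, gain = gain,
                                 noiseSd = noiseSd, seed = NULL)
      meas <- demodulateSession(ses$recordings, depthsUm, protocol)
      z <- depthZscore(meas)
      zs <- medianSmooth(z, 4L)
      truth <- .truthProfile(dens, depthsUm)
      ct <- correlateProfiles(zs, truth)
      profiles[[i]] <- z                # classification uses unsmoothed dF
      rows[[i]] <- data.frame(animal = i, genotype = genos[i],
                              rho = ct$rho, p = ct$p.value)
    }
    list(rho = do.call(rbind, rows), profiles = profiles,
         labels = factor(genos, levels = c("control", "affected")))
  })
}

#' Run a synthetic tapered-fiber cohort through the chronic pipeline
#'
#' For each recording: simulate a tracer-free day-0 session and a day-1
#' session with injection (same per-level autofluorescence drift both
#' days), demodulate both into galvo-scan matrices, fit the day-0 AF model
#' (twofold CV), subtract it from day 1, bin into 5-min bins, extract the
#' 210-240 min depth profile, and correlate it with the ground-truth
#' density at the level depths. Extrema levels (30-240 min median) are
#' z-scored against the first 25 min and read out 90 min post-injection.
#'
#' @param nAffected,nControl recording counts.
#' @param noiseSd detector noise sd per sample.
#' @param seed integer seed.
#' @param protocol tapered-fiber protocol; the default restricts the sweep
#'   to the analysed 120-uW power to keep the synthetic sessions compact.
#' @param geometry \linkS4class{TaperGeometry} of the implant.
#' @param template density template (function of DV depth).
#' @param durationS,injectionS,riseTauS session timing (s).
#' @param gain,gainSdLog fluorescence gain and per-animal spread.
#' @param levels analysis level grid.
#' @return list with \code{results} (data.frame genotype/rho/p/dMax90/
#'   dMin90), and \code{truthDensity} (per-recording generator densities).
#' @export
tfCohortStudy <- function(nAffected, nControl, noiseSd = 0.05, seed = 1,
                          protocol = tfProtocol(powers = 120),
                          geometry = TaperGeometry(tip = c(-3500, 2250,
                                                           3580)),
                          template = defaultPlaqueDensity,
                          durationS = 14700, injectionS = 1800,
                          riseTauS = 1800, gain = 0.004, gainSdLog = 0.3,
                          levels = seq(0, 4.5, length.out = 41)) {
  genos <- rep(c("affected", "control"), c(nAffected, nControl))
  if (!length(genos)) stop("cohort must contain at least one recording")
  depthsUm <- galvoAxialUm(levels, geometry)
  withSeed(seed, {
    rows <- vector("list", length(genos))
    truths <- vector("list", length(genos))
    for (i in seq_along(genos)) {
      g <- exp(rnorm(1, 0, gainSdLog))
      dens <- if (genos[i] == "affected") g * template(depthsUm)
      else rep(0, length(levels))
      aSlope <- rnorm(length(levels), -2e-5, 5e-6)
      bInt <- 1 + rnorm(length(levels), 0, 0.05)
      day0 <- simulateRecording(dens, protocol, durationS = durationS,
                                afSlope = aSlope, afIntercept = bInt,
                                injectionTimeS = NA, noiseSd = noiseSd,
                                levels = levels, seed = NULL)
      day1 <- simulateRecording(dens, protocol, durationS = durationS,
                                afSlope = aSlope, afIntercept = bInt,
                                injectionTimeS = injectionS,
                                riseTauS = riseTauS, gain = gain,
                                noiseSd = noiseSd, levels = levels,
                                seed = NULL)
      m0 <- demodulateScan(day0, protocol, levels)
      m1 <- demodulateScan(day1, protocol, levels)
      af <- fitAutofluorescence(m0)
      fm <- subtractAf(m1, af)
      binned <- binTimecourse(fm, 300)
      prof <- depthProfileWindow(binned, c(210, 240), geometry)
      truth <- .truthProfile(dens, depthsUm)
      ord <- order(depthsUm)
      ct <- spearmanTest(profileValues(prof), densities(truth)[ord])
      ext <- extremaDepths(binned, c(30, 240))
      tq <- injectionS + 90 * 60
      kq <- which.min(abs(scanTimes(binned) - tq))
      zMax <- zscoreTrace(binned, ext$maxLevel)
      zMin <- zscoreTrace(binned, ext$minLevel)
      rows[[i]] <- data.frame(recording = i, genotype = genos[i],
                              rho = ct$rho, p = ct$p.value,
                              dMax90 = zMax[kq], dMin90 = zMin[kq])
      truths[[i]] <- dens
    }
    list(results = do.call(rbind, rows), truthDensity = truths,
         depthsUm = depthsUm)
  })
}

#' Run the full synthetic study
#'
#' Generates a synthetic cohort, runs the flat-fiber pipeline with
#' photometry-versus-truth correlations, the leave-one-out genotype
#' classification, the tapered-fiber pipeline, and the group statistics
#' (pooled two-sample t on correlation coefficients; Wilcoxon signed-rank
#' on the 90-min extrema responses per genotype). Deterministic for a
#' fixed config: re-running writes a byte-identical report.
#'
#' @param config a list from \code{\link{studyConfig}}.
#' @param outDir optional output directory; when given, the report is
#'   written to \code{report.json} and a depth-profile figure to
#'   \code{depth_profiles.png}.
#' @return the report, invisibly when written, as a nested list.
#' @export
runStudy <- function(config = studyConfig(), outDir = NULL) {
  need <- names(studyConfig())
  if (!all(need %in% names(config)))
    stop("config is missing fields: ",
         paste(setdiff(need, names(config)), collapse = ", "))
  if (config$nAffectedFlat + config$nControlFlat <= 0 ||
      config$nAffectedTf + config$nControlTf <= 0)
    stop("validation error: cohorts must contain at least one animal")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed (config seed %d): %s", name,
                   config$seed, conditionMessage(e)), call. = FALSE))
  }

  flat <- stage("flat", flatCohortStudy(
    config$nAffectedFlat, config$nControlFlat, noiseSd = config$flatNoiseSd,
    seed = config$seed, gain = config$gain, gainSdLog = config$gainSdLog))
  aff <- flat$rho$rho[flat$rho$genotype == "affected"]
  ctl <- flat$rho$rho[flat$rho$genotype == "control"]
  flatT <- stage("flat-t", twoSampleT(aff, ctl))

  clf <- stage("classification", {
    pm <- buildProfileMatrix(flat$profiles, flat$labels)
    cm <- looClassify(pcaReduce(pm, 3L), pm@labels)
    c(clfMetrics(cm),
      list(hits = cm@hits, misses = cm@misses, falseAlarms = cm@falseAlarms,
           correctRejections = cm@correctRejections))
  })

  tf <- stage("tf", tfCohortStudy(
    config$nAffectedTf, config$nControlTf, noiseSd = config$tfNoiseSd,
    seed = config$seed + 1, durationS = config$tfDurationS,
    injectionS = config$tfInjectionS, riseTauS = config$riseTauS,
    gain = config$gain, gainSdLog = config$gainSdLog))
  tfa <- tf$results[tf$results$genotype == "affected", ]
  tfc <- tf$results[tf$results$genotype == "control", ]
  tfT <- stage("tf-t", twoSampleT(tfa$rho, tfc$rho))
  wAff <- stage("wilcoxon-affected",
                pairedExtremaTest(tfa$dMax90, tfa$dMin90))
  wCtl <- if (nrow(tfc) >= 2)
    stage("wilcoxon-control", pairedExtremaTest(tfc$dMax90, tfc$dMin90))
  else NULL

  report <- list(
    package = "plaquefp",
    version = as.character(utils::packageVersion("plaquefp")),
    config = config, seed = config$seed,
    stages = list(
      flat = list(nRecordings = nrow(flat$rho),
                  rho = flat$rho,
                  groupMeans = c(affected = mean(aff), control = mean(ctl)),
                  tTest = flatT),
      classification = clf,
      tf = list(nRecordings = nrow(tf$results),
                results = tf$results,
                groupMeans = c(affected = mean(tfa$rho),
                               control = mean(tfc$rho)),
                tTest = tfT,
                wilcoxonAffected = wAff,
                wilcoxonControl = wCtl)))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    grDevices::png(file.path(outDir, "depth_profiles.png"),
                   width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    plotCohortProfiles(flat$profiles, flat$labels)
    return(invisible(report))
  }
  report
}

#' Plot a cohort of z-scored depth profiles by genotype
#'
#' @param profiles list of \linkS4class{ZProfile}s.
#' @param labels genotype factor.
#' @return NULL, invisibly.
#' @export
plotCohortProfiles <- function(profiles, labels) {
  d <- depths(profiles[[1]])
  ylim <- range(vapply(profiles, function(p) range(zscores(p)),
                       numeric(2)))
  graphics::plot(NA, xlim = range(d), ylim = ylim,
                 xlab = "depth (um)", ylab = "dF (z)",
                 main = "photometry depth profiles")
  cols <- c(control = "grey40", affected = "firebrick")
  for (i in seq_along(profiles))
    graphics::lines(depths(profiles[[i]]), zscores(profiles[[i]]),
                    col = cols[as.character(labels[i])])
  graphics::legend("topleft", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(NULL)
}
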