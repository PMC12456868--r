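# Synthetic raw photometry recordings. The generating model per galvo level
# l at scan time ts is
#
#   F_l(ts) = a_l * ts + b_l                        (linear autofluorescence)
#           + gain * density_l * (1 - exp(-(ts - t_inj)/tau))   for ts >= t_inj
#
# multiplexed into a pulsed detector trace (onMs on / offMs off per pulse)
# with sync and galvo channels. The model is evaluated at the scan onset and
# held constant within the scan, and the demodulator timestamps each scan by
# its onset, so the noiseless simulate -> demodulate round trip is exact.

.tracerRise <- function(t, injectionTimeS, riseTauS) {
  if (is.na(injectionTimeS)) return(rep(0, length(t)))
  ifelse(t >= injectionTimeS, 1 - exp(-(t - injectionTimeS) / riseTauS), 0)
}

.offTissueLevels <- function(levels) {
  sp <- diff(levels)[1]
  n <- floor(1 / sp)
  if (n < 1) return(numeric(0))
  seq(-n * sp, -sp, by = sp)
}

#' Simulate a galvo-multiplexed tapered-fiber recording
#'
#' Builds a \linkS4class{RawRecording} of repeated galvo scans. Each scan
#' (one per \code{scanIntervalS}) runs, for every power and every
#' repetition, one ascending galvo sweep: a short off-tissue segment from
#' -1 V up to 0 V followed by the analysis levels, one light pulse
#' (\code{onMs} on, \code{offMs} off) per level. The detector reads the
#' per-level model fluorescence during ON periods (scaled linearly by
#' power relative to \code{max(powers)}) and the dark level 0 during OFF
#' and off-tissue periods. Acquisition is gated: only scan samples are
#' materialized, with true session times.
#'
#' @param density plaque density per analysis level (plaques/mm^3); a
#'   numeric vector of length \code{length(levels)}, a single value, or a
#'   \linkS4class{DepthProfile} with one density per level. Controls use 0.
#' @param protocol an \linkS4class{AcquisitionProtocol} (see
#'   \code{\link{tfProtocol}}).
#' @param durationS session length (s); scans start at 0, and every
#'   \code{protocol@scanIntervalS} thereafter.
#' @param afSlope,afIntercept autofluorescence coefficients (a.u./s and
#'   a.u.), scalar or per-level vectors.
#' @param injectionTimeS tracer injection time (s); NA for a tracer-free
#'   (day 0) session. Must lie within the recording when given.
#' @param riseTauS time constant of the saturating tracer rise (s); the
#'   default 1800 s reaches ~95\% of plateau 90 min post-injection.
#' @param gain fluorescence per unit plaque density at plateau
#'   (a.u. per plaques/mm^3).
#' @param noiseSd detector noise sd per sample (a.u.).
#' @param levels analysis-level voltages (default 41 levels over 0-4.5 V).
#' @param levelPowerScale per-level excitation scaling (e.g. a power
#'   calibration's PR), recycled; default 1.
#' @param seed integer seed.
#' @return a \linkS4class{RawRecording}; \code{meta$truth} carries every
#'   generating parameter and \code{meta$scanStarts} the scan onsets.
#' @seealso \code{\link{expectedScanMatrix}} for the ground-truth matrix,
#'   \code{\link{demodulateScan}} for the inverse operation.
#' @export
simulateRecording <- function(density, protocol = tfProtocol(),
                              durationS = 1800, afSlope = -2e-5,
                              afIntercept = 1, injectionTimeS = NA,
                              riseTauS = 1800, gain = 0.004, noiseSd = 0,
                              levels = seq(0, 4.5, length.out = 41),
                              levelPowerScale = 1, seed = NULL) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  if (is(density, "DepthProfile")) density <- densities(density)
  nL <- length(levels)
  if (length(density) == 1L) density <- rep(density, nL)
  if (length(density) != nL)
    stop("'density' must have one value per analysis level")
  .assertScalar(riseTauS, "riseTauS", positive = TRUE)
  if (!is.na(injectionTimeS) &&
      (injectionTimeS < 0 || injectionTimeS > durationS))
    stop("'injectionTimeS' must lie within the recording")
  a <- rep_len(afSlope, nL); b <- rep_len(afIntercept, nL)
  lps <- rep_len(levelPowerScale, nL)

  fs <- protocol@sampleRateHz
  onN <- round(fs * protocol@onMs / 1000)
  offN <- round(fs * protocol@offMs / 1000)
  pw <- protocol@powers
  refPower <- max(pw)
  sweepV <- c(.offTissueLevels(levels), levels)
  nsweep <- length(sweepV)
  pulseLen <- onN + offN
  nPulses <- length(pw) * protocol@reps * nsweep

  # per-scan template channels
  pulseSync <- c(rep(1, onN), rep(0, offN))
  syncT <- rep(pulseSync, nPulses)
  vPerPulse <- rep(sweepV, times = length(pw) * protocol@reps)
  galvoT <- rep(vPerPulse, each = pulseLen) * syncT
  idxPerPulse <- match(vPerPulse, levels)          # NA for off-tissue
  levelIdxT <- rep(idxPerPulse, each = pulseLen)
  levelIdxT[syncT == 0] <- NA
  powerT <- rep(rep(pw, each = protocol@reps * nsweep), each = pulseLen)
  scaleT <- (powerT / refPower) * syncT
  tOffT <- (seq_len(nPulses * pulseLen) - 1) / fs

  scanStarts <- seq(0, durationS, by = protocol@scanIntervalS)
  nScan <- length(scanStarts)
  chunks <- vector("list", nScan)
  onSel <- !is.na(levelIdxT)
  for (k in seq_len(nScan)) {
    ts <- scanStarts[k]
    Fl <- lps * (a * ts + b +
                   gain * density * .tracerRise(ts, injectionTimeS, riseTauS))
    det <- numeric(length(syncT))
    det[onSel] <- scaleT[onSel] * Fl[levelIdxT[onSel]]
    chunks[[k]] <- det
  }
  detector <- unlist(chunks, use.names = FALSE)
  if (noiseSd > 0)
    detector <- detector + withSeed(seed, rnorm(length(detector), 0, noiseSd))
  t <- rep(scanStarts, each = length(syncT)) + rep(tOffT, nScan)

  new("RawRecording", t = t, detector = detector,
      sync = rep(syncT, nScan), galvo = rep(galvoT, nScan),
      meta = list(protocol = protocol, levels = levels,
                  scanStarts = scanStarts, channel = "440nm",
                  truth = list(afSlope = a, afIntercept = b,
                               density = density, gain = gain,
                               injectionTimeS = injectionTimeS,
                               riseTauS = riseTauS, levelPowerScale = lps,
                               referencePowerUw = refPower),
                  seed = seed))
}

#' Ground-truth galvo-scan matrix of a simulated recording
#'
#' Evaluates the generating model of \code{\link{simulateRecording}} at the
#' recorded scan onsets, scaled to the requested power — the noiseless value
#' that demodulation should recover. Only defined for synthetic recordings
#' (it reads the embedded truth, never the detector trace).
#'
#' @param recording a \linkS4class{RawRecording} from
#'   \code{\link{simulateRecording}}.
#' @param powerUw power to scale to (default: the protocol's analysis
#'   default, 120 uW if present, else the maximum power).
#' @return a \linkS4class{GalvoScanMatrix}.
#' @export
expectedScanMatrix <- function(recording, powerUw = NULL) {
  tr <- recording@meta$truth
  if (is.null(tr)) stop("recording carries no generator ground truth")
  prot <- recording@meta$protocol
  powerUw <- powerUw %||% (if (120 %in% prot@powers) 120 else max(prot@powers))
  ts <- recording@meta$scanStarts
  lv <- recording@meta$levels
  scale <- powerUw / tr$referencePowerUw
  rise <- .tracerRise(ts, tr$injectionTimeS, tr$riseTauS)
  vals <- vapply(seq_along(ts), function(k) {
    scale * tr$levelPowerScale *
      (tr$afSlope * ts[k] + tr$afIntercept + tr$gain * tr$density * rise[k])
  }, numeric(length(lv)))
  new("GalvoScanMatrix", levels = lv, times = ts,
      values = matrix(vals, length(lv), length(ts)),
      channel = recording@meta$channel %||% "440nm", powerUw = powerUw,
      meta = list(source = "generator truth"))
}

#' Simulate a flat-fiber recording at one depth
#'
#' One power block per protocol power: a quiet baseline of
#' \code{baselineMs}, then \code{reps} pulses of \code{onMs} on /
#' \code{offMs} off. The detector reads \code{(power / max(powers)) * F}
#' during ON periods and 0 otherwise; the galvo channel is idle (0 V).
#'
#' @param F fluorescence at the reference (maximum) power (a.u.).
#' @param protocol an \linkS4class{AcquisitionProtocol} (see
#'   \code{\link{flatProtocol}}).
#' @param noiseSd detector noise sd per sample.
#' @param t0 session time of the first sample (s).
#' @param seed integer seed.
#' @return a \linkS4class{RawRecording}.
#' @export
simulateFlatRecording <- function(F, protocol = flatProtocol(), noiseSd = 0,
                                  t0 = 0, seed = NULL) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  .assertScalar(F, "F")
  fs <- protocol@sampleRateHz
  onN <- round(fs * protocol@onMs / 1000)
  offN <- round(fs * protocol@offMs / 1000)
  baseN <- round(fs * protocol@baselineMs / 1000)
  pw <- protocol@powers
  refPower <- max(pw)

  blockSync <- c(rep(0, baseN), rep(c(rep(1, onN), rep(0, offN)),
                                    protocol@reps))
  sync <- rep(blockSync, length(pw))
  scale <- rep(pw / refPower, each = length(blockSync))
  detector <- scale * sync * F
  if (noiseSd > 0)
    detector <- detector + withSeed(seed, rnorm(length(detector), 0, noiseSd))
  t <- t0 + (seq_along(sync) - 1) / fs
  new("RawRecording", t = t, detector = detector, sync = sync,
      galvo = rep(0, length(sync)),
      meta = list(protocol = protocol, channel = "440nm",
                  truth = list(F = F, referencePower = refPower),
                  seed = seed))
}

#' Simulate a flat-fiber depth-sweep session
#'
#' One recording per depth on the standard grid, visited in order at
#' \code{perDepthS} seconds per depth (the fiber is lowered between
#' measurements). The per-depth fluorescence at the reference power is
#' \code{afSlope * t + afIntercept + gain * density(depth)}: the tracer was
#' injected the day before, so the plaque signal is already at plateau and
#' only the autofluorescence drifts during the session.
#'
#' @param density densities (plaques/mm^3) on \code{depthsUm}, a single
#'   value, or a function of depth.
#' @param depthsUm depth grid (um), default \code{depthGrid()}.
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param afSlope,afIntercept autofluorescence drift (a.u./s, a.u.).
#' @param gain plateau fluorescence per unit density.
#' @param noiseSd detector noise sd per sample.
#' @param perDepthS time between successive depth measurements (s).
#' @param seed integer seed.
#' @return list with \code{recordings} (one \linkS4class{RawRecording} per
#'   depth), \code{depthsUm}, and \code{truth} (the noiseless per-depth F
#'   at reference power and the generating density).
#' @export
simulateFlatSession <- function(density, depthsUm = depthGrid(),
                                protocol = flatProtocol(), afSlope = -1e-5,
                                afIntercept = 1, gain = 0.004, noiseSd = 0,
                                perDepthS = 15, seed = NULL) {
  if (is.function(density)) density <- density(depthsUm)
  if (length(density) == 1L) density <- rep(density, length(depthsUm))
  if (length(density) != length(depthsUm))
    stop("'density' must have one value per depth")
  t0 <- (seq_along(depthsUm) - 1) * perDepthS
  Ftrue <- afSlope * t0 + afIntercept + gain * density
  recs <- withSeed(seed, lapply(seq_along(depthsUm), function(i)
    simulateFlatRecording(Ftrue[i], protocol, noiseSd = noiseSd,
                          t0 = t0[i], seed = NULL)))
  list(recordings = recs, depthsUm = depthsUm,
       truth = list(F = Ftrue, density = density, afSlope = afSlope,
                    afIntercept = afIntercept, gain = gain))
}

#' Taper transmission profile for dye calibration
#'
#' Relative excitation delivered per galvo level when the taper sits in a
#' uniform dye bath. Strictly positive (unlike the in-tissue illumination
#' envelope) so the power calibration is well defined at every level.
#'
#' @param u normalized galvo voltage in [0, 1].
#' @return relative transmission in (0, 1].
#' @export
defaultTaperTransmission <- function(u) 0.4 + 0.6 * sin(pi * u)^2

#' Simulate a uniform-dye calibration recording
#'
#' The taper is immersed in a uniform dye solution, so the demodulated
#' fluorescence per level is proportional to the taper's transmission at
#' that level; there is no drift, tracer kinetics, or depth structure.
#'
#' @param protocol an \linkS4class{AcquisitionProtocol}; the calibration
#'   default uses 5 repetitions at 60 and 80 uW.
#' @param transmission function of normalized voltage u in [0, 1] giving
#'   relative excitation per level (must be > 0).
#' @param brightness dye brightness scale (a.u.).
#' @param noiseSd detector noise sd per sample.
#' @param levels analysis-level voltages.
#' @param levelPowerScale per-level excitation scaling (apply a
#'   \linkS4class{PowerCalibration}'s PR here to verify that it equalizes
#'   fluorescence across levels).
#' @param seed integer seed.
#' @return a \linkS4class{RawRecording} containing a single scan.
#' @export
simulateDyeCalibration <- function(protocol = tfProtocol(reps = 5,
                                     powers = c(60, 80), scanIntervalS = 60),
                                   transmission = defaultTaperTransmission,
                                   brightness = 1, noiseSd = 0,
                                   levels = seq(0, 4.5, length.out = 41),
                                   levelPowerScale = 1, seed = NULL) {
  u <- (levels - min(levels)) / diff(range(levels))
  tr <- transmission(u)
  if (any(tr <= 0)) stop("transmission must be > 0 at every level")
  simulateRecording(density = 0, protocol = protocol, durationS = 0,
                    afSlope = 0, afIntercept = brightness * tr,
                    injectionTimeS = NA, noiseSd = noiseSd, levels = levels,
                    levelPowerScale = levelPowerScale, seed = seed)
}

#' Write / read a raw recording as CSV plus a JSON ground-truth sidecar
#'
#' CSV columns: \code{t, detector, sync, galvo}. Generator ground truth and
#' the level grid are written to \code{<path>.json}; the protocol itself is
#' not serialized, so \code{readRecording} takes it as an argument.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "RawRecording"))
  write.csv(data.frame(t = recording@t, detector = recording@detector,
                       sync = recording@sync, galvo = recording@galvo),
            path, row.names = FALSE)
  meta <- recording@meta
  meta$protocol <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeRecording
#' @param protocol the \linkS4class{AcquisitionProtocol} the recording was
#'   acquired with.
#' @export
readRecording <- function(path, protocol) {
  df <- read.csv(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  meta$protocol <- protocol
  new("RawRecording", t = df$t, detector = df$detector, sync = df$sync,
      galvo = df$galvo, meta = meta)
}
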