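# In vivo tapered-fiber analysis: power calibration, scan demodulation into
# a galvo-level x time matrix, autofluorescence subtraction, time binning,
# extrema-depth dynamics, z-scored traces, and depth-profile extraction.

#' Relative required power per galvo level
#'
#' From fluorescence measured in a uniform dye solution,
#' \code{PR(level) = (1/F) / min(1/F)}: the brightest level gets PR = 1 and
#' dimmer levels require proportionally more power. Scaling F by any
#' positive constant leaves PR unchanged.
#'
#' @param F mean fluorescence per galvo level (must be > 0 everywhere).
#' @param levels galvo voltages (optional; defaults to an index grid).
#' @return a \linkS4class{PowerCalibration}.
#' @export
#' @examples
#' prValues(calibratePower(c(2, 1, 4)))  # 2, 4, 1
calibratePower <- function(F, levels = seq_along(F)) {
  if (is(F, "GalvoScanMatrix")) {
    levels <- scanLevels(F)
    F <- rowMeans(scanValues(F), na.rm = TRUE)
  }
  if (any(!is.finite(F)) || any(F <= 0))
    stop("calibration fluorescence must be > 0 at every level")
  inv <- 1 / F
  new("PowerCalibration", levels = as.numeric(levels), pr = inv / min(inv))
}

#' Demodulate a galvo-scan recording into a level x time matrix
#'
#' Scans are split at acquisition gaps (sample spacing larger than
#' \code{gapFactor} sample intervals). Within each scan, ON pulses are
#' located from the sync channel; each pulse is assigned to the nearest
#' analysis level by its galvo voltage (pulses below the level grid — the
#' -1 to 0 V off-tissue segment — are discarded), restricted to the sweeps
#' of the selected power, and averaged over its interior samples (1-sample
#' edge guards) and over repetitions. Each scan is timestamped by its first
#' ON sample. Level bins that received no samples are NA and flagged in
#' \code{meta$missing}.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param protocol the \linkS4class{AcquisitionProtocol} used.
#' @param levels analysis-level grid (default 41 levels over 0-4.5 V,
#'   0.1125 V spacing).
#' @param powerSelect analysis power (default 120 uW when the protocol
#'   includes it, else the maximum power).
#' @param guard samples discarded at each pulse edge.
#' @param gapFactor scan-splitting threshold in sample intervals.
#' @return a \linkS4class{GalvoScanMatrix}.
#' @export
demodulateScan <- function(recording, protocol = tfProtocol(),
                           levels = seq(0, 4.5, length.out = 41),
                           powerSelect = NULL, guard = 1L, gapFactor = 10) {
  stopifnot(is(recording, "RawRecording"))
  if (length(recording@galvo) != length(recording@t))
    stop("galvo channel missing or mismatched")
  powerSelect <- powerSelect %||%
    (if (120 %in% protocol@powers) 120 else max(protocol@powers))
  pIdx <- which(abs(protocol@powers - powerSelect) < 1e-9)
  if (!length(pIdx)) stop("requested power not in the protocol")

  dt <- 1 / protocol@sampleRateHz
  scanId <- cumsum(c(1, diff(recording@t) > gapFactor * dt))
  nScan <- max(scanId)
  spacing <- if (length(levels) > 1) min(diff(levels)) else 1
  nL <- length(levels)
  vals <- matrix(NA_real_, nL, nScan)
  times <- numeric(nScan)

  for (s in seq_len(nScan)) {
    sel <- scanId == s
    sync <- recording@sync[sel]
    det <- recording@detector[sel]
    gal <- recording@galvo[sel]
    tt <- recording@t[sel]
    runs <- .pulseRuns(sync)
    if (!nrow(runs)) stop(sprintf("scan %d contains no pulses", s))
    times[s] <- tt[runs[1, 1]]
    nPerPower <- nrow(runs) / length(protocol@powers)
    if (nPerPower != round(nPerPower))
      stop("pulse count is not a multiple of the number of powers")
    block <- (pIdx - 1) * nPerPower + seq_len(nPerPower)
    acc <- vector("list", nL)
    for (r in block) {
      i0 <- runs[r, 1]; i1 <- runs[r, 2]
      v <- median(gal[i0:i1])
      if (v < levels[1] - spacing / 2) next        # off-tissue sweep segment
      li <- which.min(abs(levels - v))
      ii <- (i0 + guard):(i1 - guard)
      acc[[li]] <- c(acc[[li]], mean(det[ii]))
    }
    got <- lengths(acc) > 0
    vals[got, s] <- vapply(acc[got], mean, numeric(1))
  }
  missing <- which(is.na(vals), arr.ind = TRUE)
  new("GalvoScanMatrix", levels = levels, times = times, values = vals,
      channel = recording@meta$channel %||% "440nm", powerUw = powerSelect,
      meta = list(missing = missing, guard = guard))
}

#' Fit the per-level linear autofluorescence model on a day-0 session
#'
#' At each galvo level, the tracer-free fluorescence is fit as
#' \code{F ~ a t + b} by twofold cross-validation: timepoints are split
#' into interleaved (odd/even) folds, each fold is fit by least squares,
#' the coefficients are averaged across folds, and \code{cvError} is the
#' mean held-out squared error.
#'
#' @param day0 a \linkS4class{GalvoScanMatrix} from a session without
#'   tracer administration, with at least 4 timepoints per level.
#' @return an \linkS4class{AFModel}.
#' @export
fitAutofluorescence <- function(day0) {
  stopifnot(is(day0, "GalvoScanMatrix"))
  nL <- length(day0@levels)
  a <- b <- e <- numeric(nL)
  for (l in seq_len(nL)) {
    ok <- which(!is.na(day0@values[l, ]))
    if (length(ok) < 4)
      stop(sprintf("level %d has fewer than 4 timepoints", l))
    t <- day0@times[ok]; y <- day0@values[l, ok]
    folds <- list(ok = seq_along(ok) %% 2 == 1,
                  other = seq_along(ok) %% 2 == 0)
    co <- matrix(0, 2, 2)
    err <- numeric(2)
    for (f in 1:2) {
      tr <- folds[[f]]
      if (sum(tr) < 2) stop("fewer than 2 points per fold")
      fit <- lm(y[tr] ~ t[tr])
      co[, f] <- unname(coef(fit))
      pred <- co[1, f] + co[2, f] * t[!tr]
      err[f] <- mean((y[!tr] - pred)^2)
    }
    b[l] <- mean(co[1, ]); a[l] <- mean(co[2, ]); e[l] <- mean(err)
  }
  new("AFModel", levels = day0@levels, slopes = a, intercepts = b,
      cvError = e)
}

#' Subtract the predicted autofluorescence from a day-1 session
#'
#' \code{Fm(level, t) = F(level, t) - (a(level) t + b(level))}, with t on
#' the day-1 session clock (sessions share their structure, so the day-0
#' model extrapolates with t measured from session start).
#'
#' @param day1 a \linkS4class{GalvoScanMatrix}.
#' @param model an \linkS4class{AFModel} on the same level grid.
#' @return a \linkS4class{GalvoScanMatrix} of tracer-attributable signal.
#' @export
subtractAf <- function(day1, model) {
  stopifnot(is(day1, "GalvoScanMatrix"), is(model, "AFModel"))
  if (length(day1@levels) != length(model@levels) ||
      max(abs(day1@levels - model@levels)) > 1e-9)
    stop("level grids of the session and the AF model do not match")
  af <- outer(model@slopes, day1@times) + model@intercepts
  meta <- day1@meta
  meta$afSubtracted <- TRUE
  new("GalvoScanMatrix", levels = day1@levels, times = day1@times,
      values = day1@values - af, channel = day1@channel,
      powerUw = day1@powerUw, meta = meta)
}

#' Bin a level x time matrix into fixed time bins
#'
#' Per-(level, bin) mean with NAs excluded. Bins are
#' \code{[k binS, (k+1) binS)} from the session start; a partial trailing
#' bin is kept and flagged in \code{meta$partialTrailing}. Each bin is
#' timestamped by the mean of its scan times, so a linear signal keeps its
#' value at the bin timestamp exactly.
#'
#' @param gsm a \linkS4class{GalvoScanMatrix}.
#' @param binS bin width (s), default 300 (5 min).
#' @return a binned \linkS4class{GalvoScanMatrix}.
#' @export
binTimecourse <- function(gsm, binS = 300) {
  stopifnot(is(gsm, "GalvoScanMatrix"))
  .assertScalar(binS, "binS", positive = TRUE)
  idx <- floor(gsm@times / binS)
  bins <- sort(unique(idx))
  vals <- vapply(bins, function(bn)
    rowMeans(gsm@values[, idx == bn, drop = FALSE], na.rm = TRUE),
    numeric(length(gsm@levels)))
  vals[is.nan(vals)] <- NA_real_
  btimes <- vapply(bins, function(bn) mean(gsm@times[idx == bn]), numeric(1))
  meta <- gsm@meta
  meta$binS <- binS
  meta$partialTrailing <- max(gsm@times) < (bins[length(bins)] + 1) * binS
  new("GalvoScanMatrix", levels = gsm@levels, times = btimes,
      values = matrix(vals, length(gsm@levels), length(bins)),
      channel = gsm@channel, powerUw = gsm@powerUw, meta = meta)
}

#' Galvo levels with extreme median signal in a time window
#'
#' Per level, the median of the bins whose timestamps fall inside the
#' window (minutes, closed); returns the levels attaining the maximum and
#' minimum. Ties break toward the lower level index.
#'
#' @param binned a binned \linkS4class{GalvoScanMatrix}.
#' @param windowMin time window in minutes (default 30-240).
#' @return list with \code{maxLevel}, \code{minLevel} (indices),
#'   \code{maxVoltage}, \code{minVoltage}, and \code{medians} per level.
#' @export
extremaDepths <- function(binned, windowMin = c(30, 240)) {
  stopifnot(is(binned, "GalvoScanMatrix"))
  .assertRange(windowMin, "windowMin")
  sel <- binned@times >= windowMin[1] * 60 & binned@times <= windowMin[2] * 60
  if (!any(sel)) stop("no bins inside the window")
  med <- apply(binned@values[, sel, drop = FALSE], 1, median, na.rm = TRUE)
  list(maxLevel = which.max(med), minLevel = which.min(med),
       maxVoltage = binned@levels[which.max(med)],
       minVoltage = binned@levels[which.min(med)],
       medians = med)
}

#' Z-score and smooth the timecourse at one galvo level
#'
#' dF = (Fm - mean(F0)) / sd(F0) with F0 the bins in the first
#' \code{baselineMin} minutes of the recording (timestamps < baselineMin),
#' followed by a moving median (window 3 by default).
#'
#' @param binned a binned \linkS4class{GalvoScanMatrix}.
#' @param level level index (row).
#' @param baselineMin baseline duration (minutes).
#' @param smoothWindow moving-median window (bins); 1 disables smoothing.
#' @return numeric dF trace with attribute \code{times} (s).
#' @export
zscoreTrace <- function(binned, level, baselineMin = 25, smoothWindow = 3L) {
  stopifnot(is(binned, "GalvoScanMatrix"))
  x <- binned@values[level, ]
  base <- x[binned@times < baselineMin * 60]
  base <- base[!is.na(base)]
  if (length(base) < 2) stop("need at least 2 baseline bins")
  s <- sd(base)
  if (s == 0) stop("degenerate baseline: zero standard deviation")
  dF <- (x - mean(base)) / s
  structure(movingMedian(dF, smoothWindow), times = binned@times)
}

#' Depth profile of tracer signal over a late time window
#'
#' Per level, the mean Fm over the bins whose timestamps fall inside the
#' window (minutes, closed; default 210-240 min). Positions are DV depths
#' via the affine galvo-to-depth map when a geometry is supplied, else the
#' galvo voltages themselves. The 600-um histology track shift belongs to
#' the histology profile (see \code{\link{shiftTrack}}), not to this map.
#'
#' @param binned a binned \linkS4class{GalvoScanMatrix}.
#' @param windowMin time window in minutes.
#' @param geometry optional \linkS4class{TaperGeometry} for depth mapping.
#' @param orientation sweep orientation (see \code{\link{galvoAxialUm}}).
#' @return an \linkS4class{AxialProfile} (kind photometry).
#' @export
depthProfileWindow <- function(binned, windowMin = c(210, 240),
                               geometry = NULL,
                               orientation = "shallow-to-deep") {
  stopifnot(is(binned, "GalvoScanMatrix"))
  .assertRange(windowMin, "windowMin")
  sel <- binned@times >= windowMin[1] * 60 & binned@times <= windowMin[2] * 60
  if (!any(sel)) stop("the window lies outside the recording")
  prof <- rowMeans(binned@values[, sel, drop = FALSE], na.rm = TRUE)
  pos <- if (is.null(geometry)) binned@levels
  else galvoAxialUm(binned@levels, geometry, orientation = orientation)
  ord <- order(pos)
  AxialProfile(positions = pos[ord], values = prof[ord], kind = "photometry")
}

# Exact two-sided sign-flip p-value for the signed-rank statistic with
# average ranks. Doubled ranks are integers, so the permutation
# distribution of 2V is built by polynomial convolution over the 2^n sign
# assignments (feasible for the n <= 25 used here). Ties are handled
# exactly, which stats::wilcox.test's exact path does not support.
.signedRankExactP <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  v2 <- sum(r2[d > 0])
  S <- sum(r2)
  counts <- c(1, rep(0, S))
  for (ri in r2)
    counts <- counts + c(rep(0, ri), counts[seq_len(S + 1 - ri)])
  dev <- abs(v2 - S / 2) - 1e-9
  s <- 0:S
  list(V = v2 / 2, p = sum(counts[abs(s - S / 2) >= dev]) / sum(counts))
}

#' Paired Wilcoxon signed-rank test on extrema-depth responses
#'
#' Two-sided Wilcoxon signed-rank test on per-recording differences
#' between the maximum- and minimum-depth z-scored responses at a stated
#' timepoint. Zero differences are dropped (with a warning); for n <= 25
#' the p-value is exact by full enumeration of the sign-flip distribution
#' (tie-aware, via average ranks), otherwise the normal approximation is
#' used. All-zero differences return p = 1 with a warning.
#'
#' @param dMax,dMin paired per-recording values.
#' @return list with \code{statistic} (V, the positive-rank sum),
#'   \code{p.value}, \code{n} (non-zero pairs), \code{method}.
#' @export
pairedExtremaTest <- function(dMax, dMin) {
  if (length(dMax) != length(dMin)) stop("pairs must have equal length")
  d <- dMax - dMin
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, n = length(d),
                method = "Wilcoxon signed-rank (degenerate: all zeros)"))
  }
  if (any(d == 0)) {
    warning(sprintf("%d zero difference(s) dropped", sum(d == 0)))
    d <- d[d != 0]
  }
  n <- length(d)
  if (n <= 25) {
    ex <- .signedRankExactP(d)
    list(statistic = ex$V, p.value = ex$p, n = n,
         method = "Wilcoxon signed-rank (exact sign-flip enumeration)")
  } else {
    wt <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n,
         method = "Wilcoxon signed-rank (normal approximation)")
  }
}
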