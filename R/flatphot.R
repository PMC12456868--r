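# Flat-fiber photometry: demodulation, depth z-scoring, smoothing, and
# comparison against histological depth profiles.

# interior ON samples of each pulse (runs of sync == 1), discarding `guard`
# samples at each edge as a slew guard
.pulseRuns <- function(sync) {
  r <- rle(sync)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- r$values == 1
  cbind(start = starts[on], end = ends[on])
}

#' Demodulate a flat-fiber recording
#'
#' Pulses are located from the sync channel; each pulse's fluorescence is
#' the mean of the detector samples strictly inside the ON window (the
#' first and last \code{guard} samples are discarded as transition guards,
#' so a 10-ms pulse at 5000 Hz contributes 48 of its 50 samples). Pulses
#' are grouped into consecutive blocks of \code{protocol@reps} per power,
#' in protocol order, and averaged within each block.
#'
#' @param recording a \linkS4class{RawRecording} from one depth.
#' @param protocol the \linkS4class{AcquisitionProtocol} used.
#' @param guard samples discarded at each pulse edge (default 1).
#' @param statistic how repetitions are combined (the mean by default; the
#'   median is available).
#' @return data.frame with one row per power: \code{power, F}.
#' @export
demodulate <- function(recording, protocol = flatProtocol(), guard = 1L,
                       statistic = c("mean", "median")) {
  stopifnot(is(recording, "RawRecording"))
  statistic <- match.arg(statistic)
  if (length(recording@sync) != length(recording@detector))
    stop("sync and detector length mismatch")
  runs <- .pulseRuns(recording@sync)
  if (!nrow(runs)) stop("no complete pulse found in the recording")
  nExp <- length(protocol@powers) * protocol@reps
  if (nrow(runs) != nExp)
    stop(sprintf("found %d pulses, protocol implies %d", nrow(runs), nExp))
  perPulse <- apply(runs, 1, function(r) {
    i <- (r[1] + guard):(r[2] - guard)
    if (length(i) < 1 || i[1] > i[length(i)])
      stop("pulse too short for the guard setting")
    mean(recording@detector[i])
  })
  block <- rep(seq_along(protocol@powers), each = protocol@reps)
  agg <- if (statistic == "mean") tapply(perPulse, block, mean)
  else tapply(perPulse, block, median)
  data.frame(power = protocol@powers, F = as.numeric(agg))
}

#' Demodulate a flat-fiber depth sweep into per-depth fluorescence
#'
#' Convenience wrapper: demodulates one recording per depth and keeps the
#' fluorescence at the requested analysis power (default: the maximum,
#' 1 mW/mm2 under the standard protocol).
#'
#' @param recordings list of \linkS4class{RawRecording}, one per depth.
#' @param depthsUm matching depths (um).
#' @param protocol the \linkS4class{AcquisitionProtocol} used.
#' @param power analysis power; default \code{max(protocol@powers)}.
#' @param ... passed to \code{\link{demodulate}}.
#' @return data.frame with \code{depth_um, F}.
#' @export
demodulateSession <- function(recordings, depthsUm,
                              protocol = flatProtocol(), power = NULL, ...) {
  if (length(recordings) != length(depthsUm))
    stop("one recording per depth required")
  power <- power %||% max(protocol@powers)
  F <- vapply(recordings, function(r) {
    d <- demodulate(r, protocol, ...)
    i <- which(abs(d$power - power) < 1e-9)
    if (!length(i)) stop("requested power not in the protocol")
    d$F[i]
  }, numeric(1))
  data.frame(depth_um = depthsUm, F = F)
}

#' Z-score a fluorescence depth profile against its superficial baseline
#'
#' dF = (F - mean(F0)) / sd(F0), where F0 collects the measurements at
#' depths inside the closed baseline window (0-400 um by default: 5 depths
#' on the 100-um grid). A zero baseline standard deviation raises an error
#' rather than emitting infinities.
#'
#' @param depthsUm depth grid (um), or a data.frame with \code{depth_um, F}.
#' @param F fluorescence per depth (ignored when a data.frame is given).
#' @param baselineRangeUm closed baseline window (um).
#' @return a \linkS4class{ZProfile}.
#' @export
depthZscore <- function(depthsUm, F = NULL, baselineRangeUm = c(0, 400)) {
  if (is.data.frame(depthsUm)) {
    F <- depthsUm$F
    depthsUm <- depthsUm$depth_um
  }
  .assertRange(baselineRangeUm, "baselineRangeUm")
  if (length(depthsUm) != length(F)) stop("one F per depth required")
  base <- F[depthsUm >= baselineRangeUm[1] & depthsUm <= baselineRangeUm[2]]
  if (length(base) < 2)
    stop("need at least 2 depths inside the baseline window")
  s <- sd(base)
  if (s == 0)
    stop("degenerate baseline: zero standard deviation over the window")
  new("ZProfile", depth = as.numeric(depthsUm), dF = (F - mean(base)) / s,
      baselineWindowUm = baselineRangeUm, meta = list())
}

#' Median-filter a z-scored depth profile
#'
#' Moving median of window size 4 by default. An even window has no
#' canonical alignment; the window at index i covers \code{[i-1, i+2]},
#' truncated at the edges (see \code{\link{movingMedian}}).
#'
#' @param profile a \linkS4class{ZProfile} (or numeric vector).
#' @param window window size (>= 1).
#' @return same type as the input, smoothed.
#' @export
medianSmooth <- function(profile, window = 4L) {
  if (is.numeric(profile)) return(movingMedian(profile, window))
  stopifnot(is(profile, "ZProfile"))
  meta <- profile@meta
  meta$filterWindow <- window
  new("ZProfile", depth = profile@depth,
      dF = movingMedian(profile@dF, window),
      baselineWindowUm = profile@baselineWindowUm, meta = meta)
}

#' Correlate a photometry depth profile with a histology profile
#'
#' Spearman rank correlation (see \code{\link{spearmanTest}}) between the
#' z-scored photometry profile and the plaque-density profile. The grids
#' must share their step by construction; the histology profile is matched
#' to the photometry grid by nearest depth (within half a step).
#'
#' @param photometry a \linkS4class{ZProfile}.
#' @param histology a \linkS4class{DepthProfile}.
#' @return list with \code{rho}, \code{p.value}, \code{n}, \code{method}.
#' @export
correlateProfiles <- function(photometry, histology) {
  stopifnot(is(photometry, "ZProfile"), is(histology, "DepthProfile"))
  dp <- depths(photometry); dh <- depths(histology)
  idx <- vapply(dp, function(d) which.min(abs(dh - d)), integer(1))
  step <- if (length(dp) > 1) min(diff(sort(dp))) else Inf
  if (any(abs(dh[idx] - dp) > step / 2 + 1e-9))
    stop("photometry and histology grids do not align")
  spearmanTest(zscores(photometry), densities(histology)[idx])
}
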