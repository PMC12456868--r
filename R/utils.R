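# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generators do not
#' disturb the caller's RNG stream. A \code{NULL} seed leaves the global
#' stream untouched (and advances it).
#'
#' @param seed integer seed or \code{NULL}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.assertScalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

.assertRange <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[2] <= x[1])
    stop(sprintf("'%s' must be a finite, increasing length-2 range", name))
  invisible(x)
}

#' Moving median with truncated asymmetric windows
#'
#' For window size w the window at index i covers
#' \code{[i - floor((w-1)/2), i + ceiling((w-1)/2)]}, truncated at the
#' edges; for the even window 4 this is \code{[i-1, i+2]}, for the odd
#' window 3 the usual centered \code{[i-1, i+1]}. Output length equals
#' input length. NAs are dropped within each window.
#'
#' @param x numeric vector.
#' @param window integer window size (>= 1).
#' @return numeric vector of the same length as \code{x}.
#' @export
#' @examples
#' movingMedian(c(1, 9, 2, 8, 3, 7), window = 4)
movingMedian <- function(x, window = 4L) {
  .assertScalar(window, "window", positive = TRUE)
  window <- as.integer(window)
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - lo):min(n, i + hi)]
    out[i] <- median(w, na.rm = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Common depth grid: 0 to 4000 um at 100-um steps gives the 41 depths used
# throughout the flat-fiber analysis.

#' Depth grid along the penetration
#'
#' @param fromUm,toUm depth range in micrometers.
#' @param byUm step in micrometers.
#' @return numeric vector of depths.
#' @export
#' @examples
#' length(depthGrid())  # 41
depthGrid <- function(fromUm = 0, toUm = 4000, byUm = 100) {
  .assertScalar(byUm, "byUm", positive = TRUE)
  seq(fromUm, toUm, by = byUm)
}

#' Axial span covered by a galvo scan
#'
#' \code{nSteps} galvo levels at \code{stepUm} per level span
#' \code{(nSteps - 1) * stepUm} micrometers (fence-post counting: 41 steps
#' every 39.5 um span 1580 um, i.e. ~1.6 mm of taper).
#'
#' @param nSteps number of galvo levels.
#' @param stepUm axial distance between adjacent levels (um).
#' @return span in micrometers.
#' @export
galvoSpanUm <- function(nSteps = 41, stepUm = 39.5) {
  .assertScalar(nSteps, "nSteps", positive = TRUE)
  .assertScalar(stepUm, "stepUm", positive = TRUE)
  (nSteps - 1) * stepUm
}
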