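# Shared statistics used by the flat-fiber, ex vivo and in vivo analyses.
# A single Spearman implementation serves all three so cross-stage results
# are comparable by construction.

#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes Spearman's rho with average ranks for ties. The two-sided
#' p-value is exact for n <= 10 (full enumeration of rank permutations,
#' tie-aware) and uses the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on \code{n - 2} degrees of
#' freedom otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no NAs, neither
#'   constant.
#' @return list with \code{rho}, \code{p.value}, \code{n}, \code{method}.
#' @export
#' @examples
#' spearmanTest(1:6, c(2, 1, 4, 3, 6, 5))
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("rho is undefined for constant input")
  rho <- cor(rx, ry)
  if (n <= 10) {
    p <- .spearmanPermPvalue(rx, ry)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    if (abs(rho) >= 1) p <- 0
    else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "Spearman rank correlation (t approximation)"
  }
  list(rho = rho, p.value = p, n = n, method = method)
}

.pooledT <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("zero pooled variance: t is undefined")
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tstat, df = df, p.value = 2 * pt(-abs(tstat), df),
       method = "two-sample t (pooled variance)",
       groupMeans = c(m1, m2), n = c(n1, n2))
}

#' Two-sample pooled-variance t-test
#'
#' Student's t with pooled variance and \code{n1 + n2 - 2} degrees of
#' freedom, two-sided.
#'
#' @param a,b numeric vectors of group values (each n >= 2).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{method}, \code{groupMeans}, \code{n}.
#' @seealso \code{\link{twoSampleTFromSummary}} for published
#'   (mean, SEM, n) summaries.
#' @export
twoSampleT <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  .pooledT(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' @rdname twoSampleT
#' @param meanA,meanB group means.
#' @param semA,semB group standard errors of the mean; the group SD is
#'   reconstructed as \code{SEM * sqrt(n)}.
#' @param nA,nB group sizes.
#' @export
#' @examples
#' # summary statistics reported as mean +/- SEM per group
#' twoSampleTFromSummary(0.499, 0.081, 13, -0.101, 0.061, 11)$statistic
twoSampleTFromSummary <- function(meanA, semA, nA, meanB, semB, nB) {
  .pooledT(meanA, semA * sqrt(nA), nA, meanB, semB * sqrt(nB), nB)
}

#' Duty cycle of an acquisition protocol
#'
#' Fraction of each pulse period during which the light source is on:
#' \code{onMs / (onMs + offMs)}; 10 ms on / 5 ms off gives 2/3 (~67\%).
#'
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @return duty cycle in [0, 1].
#' @export
dutyCycle <- function(protocol) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  protocol@onMs / (protocol@onMs + protocol@offMs)
}
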