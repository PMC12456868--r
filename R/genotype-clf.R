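# Genotype classification from photometry depth profiles: per-profile
# z-scoring, PCA to 3 components, leave-one-out linear SVM, confusion
# metrics. Positive class: affected.

.zrow <- function(x) {
  s <- sd(x)
  if (s == 0) stop("zero-variance profile cannot be z-scored")
  (x - mean(x)) / s
}

#' Assemble a labelled profile matrix for classification
#'
#' Stacks depth profiles into a samples x depths matrix and z-scores each
#' row (mean 0, sample sd 1). All profiles must share one grid (41 depths
#' under the default protocol). Classification uses the unsmoothed dF
#' profiles.
#'
#' @param profiles list of \linkS4class{ZProfile} objects (or numeric
#'   vectors on a common grid, or a numeric matrix).
#' @param labels genotype per sample, coerced to factor with levels
#'   \code{control}, \code{affected}.
#' @return a \linkS4class{ProfileMatrix}.
#' @export
buildProfileMatrix <- function(profiles, labels) {
  if (is.matrix(profiles)) {
    m <- profiles
  } else {
    rows <- lapply(profiles, function(p) {
      if (is(p, "ZProfile")) zscores(p) else as.numeric(p)
    })
    if (is(profiles[[1]], "ZProfile")) {
      g <- depths(profiles[[1]])
      ok <- vapply(profiles, function(p) is(p, "ZProfile") &&
                     length(depths(p)) == length(g) &&
                     max(abs(depths(p) - g)) < 1e-9, logical(1))
      if (!all(ok)) stop("all profiles must share one depth grid")
    } else if (length(unique(lengths(rows))) != 1L) {
      stop("all profiles must share one depth grid")
    }
    m <- do.call(rbind, rows)
  }
  if (nrow(m) != length(labels)) stop("one label per profile required")
  z <- t(apply(m, 1, .zrow))
  labels <- factor(as.character(labels), levels = c("control", "affected"))
  if (any(is.na(labels))) stop("labels must be 'control' or 'affected'")
  new("ProfileMatrix", values = z, labels = labels)
}

#' Reduce a profile matrix to its leading principal components
#'
#' Column-centered PCA (no column scaling); returns the score matrix of the
#' top \code{k} components ordered by explained variance, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param pm a \linkS4class{ProfileMatrix} (or plain matrix).
#' @param k number of components (default 3); must not exceed
#'   \code{min(nrow - 1, ncol)}.
#' @return samples x k score matrix with attributes \code{sdev} (all
#'   component standard deviations) and \code{rotation} (the k loadings).
#' @export
pcaReduce <- function(pm, k = 3L) {
  m <- if (is(pm, "ProfileMatrix")) pm@values else as.matrix(pm)
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (k > kmax)
    stop(sprintf("k = %d exceeds the maximum rank %d", k, kmax))
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sc <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  structure(sc, sdev = pr$sdev, rotation = rot)
}

#' Leave-one-out SVM genotype classification
#'
#' For each sample, a support vector machine is trained on all remaining
#' samples and predicts the held-out sample; predictions are tallied into a
#' confusion matrix with \code{affected} as the positive class. The kernel
#' is linear with cost 1 by default. Deterministic for a fixed
#' configuration.
#'
#' @param scores samples x d numeric matrix (PCA scores).
#' @param labels factor with levels \code{control}, \code{affected};
#'   at least 2 samples per class.
#' @param kernel,cost SVM configuration (see \code{\link[e1071]{svm}}).
#' @param scale whether the SVM rescales features per fold (default FALSE:
#'   PCA scores are already commensurate).
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
looClassify <- function(scores, labels, kernel = "linear", cost = 1,
                        scale = FALSE) {
  scores <- as.matrix(scores)
  labels <- factor(as.character(labels), levels = c("control", "affected"))
  n <- nrow(scores)
  if (n != length(labels)) stop("one label per sample required")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  pred <- character(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(labels[-i])
    if (nlevels(ytr) < 2)
      stop(sprintf("training fold for sample %d has a single class", i))
    fit <- e1071::svm(scores[-i, , drop = FALSE], labels[-i],
                      kernel = kernel, cost = cost, scale = scale)
    pred[i] <- as.character(predict(fit, scores[i, , drop = FALSE]))
  }
  ConfusionMatrix(
    hits = sum(pred == "affected" & labels == "affected"),
    misses = sum(pred == "control" & labels == "affected"),
    falseAlarms = sum(pred == "affected" & labels == "control"),
    correctRejections = sum(pred == "control" & labels == "control"))
}

#' Classify genotypes from a profile matrix (PCA + leave-one-out SVM)
#'
#' Convenience wrapper chaining \code{\link{pcaReduce}} and
#' \code{\link{looClassify}}. By default the PCA is fitted once on all
#' samples before the leave-one-out loop — matching the study design this
#' package follows, at the cost of a mild information leak from the
#' held-out sample into the (unsupervised) projection. Set
#' \code{pcaPerFold = TRUE} to refit the projection inside every fold,
#' which removes the leak.
#'
#' @param pm a \linkS4class{ProfileMatrix}.
#' @param k number of principal components (default 3).
#' @param pcaPerFold refit PCA within each training fold (default FALSE).
#' @param kernel,cost,scale SVM configuration (see \code{\link{looClassify}}).
#' @return a \linkS4class{ConfusionMatrix}.
#' @export
classifyGenotypes <- function(pm, k = 3L, pcaPerFold = FALSE,
                              kernel = "linear", cost = 1, scale = FALSE) {
  stopifnot(is(pm, "ProfileMatrix"))
  labels <- pm@labels
  if (!pcaPerFold)
    return(looClassify(pcaReduce(pm, k), labels, kernel = kernel,
                       cost = cost, scale = scale))
  X <- pm@values
  n <- nrow(X)
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  pred <- character(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(labels[-i])
    if (nlevels(ytr) < 2)
      stop(sprintf("training fold for sample %d has a single class", i))
    ctr <- colMeans(X[-i, , drop = FALSE])
    sc <- pcaReduce(X[-i, , drop = FALSE], k)
    rot <- attr(sc, "rotation")
    fit <- e1071::svm(matrix(sc, nrow(sc), k), labels[-i],
                      kernel = kernel, cost = cost, scale = scale)
    heldOut <- matrix(X[i, ] - ctr, 1) %*% rot
    pred[i] <- as.character(predict(fit, heldOut))
  }
  ConfusionMatrix(
    hits = sum(pred == "affected" & labels == "affected"),
    misses = sum(pred == "control" & labels == "affected"),
    falseAlarms = sum(pred == "affected" & labels == "control"),
    correctRejections = sum(pred == "control" & labels == "control"))
}

#' Classification performance metrics
#'
#' Overall accuracy, hit rate (sensitivity for the affected class) and
#' correct-rejection rate (specificity), as percentages to one decimal.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return list with \code{accuracy}, \code{hitRate},
#'   \code{correctRejectionRate} (percent).
#' @export
#' @examples
#' clfMetrics(ConfusionMatrix(10, 3, 1, 10))
clfMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  pos <- cm@hits + cm@misses
  neg <- cm@falseAlarms + cm@correctRejections
  if (pos == 0 || neg == 0) stop("both classes must be represented")
  list(accuracy = round(100 * (cm@hits + cm@correctRejections) /
                          (pos + neg), 1),
       hitRate = round(100 * cm@hits / pos, 1),
       correctRejectionRate = round(100 * cm@correctRejections / neg, 1))
}

#' Generate a synthetic cohort of classification profiles
#'
#' Lightweight profile-level cohort generator for classification studies:
#' affected samples follow the depth-density template (scaled by
#' \code{effectSize} and a per-animal lognormal gain) plus unit-free
#' Gaussian depth noise; control samples are noise only. Profiles are
#' returned un-z-scored; \code{\link{buildProfileMatrix}} standardizes
#' them.
#'
#' @param nAffected,nControl cohort sizes.
#' @param effectSize multiplier on the template amplitude (1 = generator
#'   default; 0 = no genotype signal).
#' @param noiseSd per-depth noise sd (in template-amplitude units).
#' @param depthsUm depth grid (default \code{depthGrid()}).
#' @param template density template as a function of depth.
#' @param gainSdLog sd of the per-animal lognormal gain.
#' @param seed integer seed.
#' @return list with \code{profiles} (matrix) and \code{labels} (factor).
#' @export
makeCohortProfiles <- function(nAffected, nControl, effectSize = 1,
                               noiseSd = 1, depthsUm = depthGrid(),
                               template = defaultPlaqueDensity,
                               gainSdLog = 0.3, seed = NULL) {
  shape <- template(depthsUm)
  shape <- (shape - mean(shape)) / sd(shape)
  nd <- length(depthsUm)
  withSeed(seed, {
    aff <- t(vapply(seq_len(nAffected), function(i)
      effectSize * exp(rnorm(1, 0, gainSdLog)) * shape + rnorm(nd, 0, noiseSd),
      numeric(nd)))
    ctl <- t(vapply(seq_len(nControl), function(i) rnorm(nd, 0, noiseSd),
                    numeric(nd)))
    list(profiles = rbind(aff, ctl),
         labels = factor(rep(c("affected", "control"),
                             c(nAffected, nControl)),
                         levels = c("control", "affected")))
  })
}
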