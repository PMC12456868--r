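# Shared fixtures and independent oracles used across test files.

# brute-force Spearman rho: explicit average ranks, then the Pearson
# product-moment formula written out as sums (independent of cor())
bruteSpearman <- function(x, y) {
  avgRank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- avgRank(x); ry <- avgRank(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  num <- n * sum(rx * ry) - sx * sy
  den <- sqrt(n * sum(rx^2) - sx^2) * sqrt(n * sum(ry^2) - sy^2)
  num / den
}

# O(N*M) pairwise-distance counting oracle for depth/ROI profiles
bruteBallCounts <- function(points, centers, radius) {
  vapply(seq_len(nrow(centers)), function(i) {
    n <- 0
    for (j in seq_len(nrow(points))) {
      if (sqrt(sum((points[j, ] - centers[i, ])^2)) <= radius + 1e-9)
        n <- n + 1
    }
    n
  }, numeric(1))
}

# plaque field with hand-placed, well-separated centroids (no Poisson draw)
fixedPlaqueField <- function(points, diameters,
                             volumeUm = rbind(AP = c(-5000, 0),
                                              ML = c(0, 5000),
                                              DV = c(0, 4000))) {
  new("PlaqueField", points = points, diameters = diameters,
      genotype = "affected", volumeUm = volumeUm, meta = list())
}

testGeometry <- function() TaperGeometry(tip = c(-3500, 2250, 3580))

# compact TF protocol for fast synthetic sessions
testTfProtocol <- function(...) tfProtocol(powers = 120, ...)
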