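## Independent oracles and small fixture builders used across the suite.

## random symmetric banded dense matrix with mixed-sign entries
randBandMatrix <- function(p, h, sd = 1) {
  M <- matrix(rnorm(p * p, sd = sd), p)
  M <- (M + t(M)) / 2
  M[abs(row(M) - col(M)) >= h] <- 0
  M
}

## brute-force S(C) over C = [i, j) from a dense matrix
bruteIntervalSum <- function(M, i, j) sum(M[i:(j - 1), i:(j - 1)])

## brute-force Ward linkage via the similarity form
bruteWard <- function(M, i, m, j) {
  bruteIntervalSum(M, i, m) / (m - i) + bruteIntervalSum(M, m, j) / (j - m) -
    bruteIntervalSum(M, i, j) / (j - i)
}

## classical Ward ESS-increase oracle for Euclidean points (rows of X):
## |C||C'|/(|C|+|C'|) * ||mean(C) - mean(C')||^2
essWard <- function(X, i, m, j) {
  a <- colMeans(X[i:(m - 1), , drop = FALSE])
  b <- colMeans(X[m:(j - 1), , drop = FALSE])
  nl <- m - i; nr <- j - m
  nl * nr / (nl + nr) * sum((a - b)^2)
}

## merge-sequence comparison (intervals only, heights separately)
sameMergeSequence <- function(D1, D2) {
  isTRUE(all.equal(merges(D1)[, c("i", "m", "j")],
                   merges(D2)[, c("i", "m", "j")]))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## left-to-right chain dendrogram with prescribed heights (step s merges
## [1, s+1) with {s+1}); used to hand-build criterion traces
chainDendrogram <- function(heights) {
  n <- length(heights)
  p <- n + 1L
  mg <- matrix(0, n, 8,
               dimnames = list(NULL, c("leftRef", "rightRef", "i", "m", "j",
                                       "height", "sizeLeft", "sizeRight")))
  for (s in seq_len(n))
    mg[s, ] <- c(if (s == 1) -1 else s - 1, -(s + 1), 1, s + 1, s + 2,
                 heights[s], s, 1)
  bandclust:::newDendrogram(p, mg)
}

## band-storage random similarity for sizes where a dense p x p matrix is
## impractical: positive diagonal, N(0,1) off-diagonals, zero edge padding
randBandSim <- function(p, h) {
  band <- matrix(rnorm(p * h), p, h)
  band[, 1] <- abs(band[, 1]) + 1
  for (d in seq_len(h - 1))
    if (p - d + 1 <= p) band[(p - d + 1):p, d + 1] <- 0
  bandclust:::newBandSimilarity(band)
}
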