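#' @include Dendrogram-class.R FusionHeap.R
NULL

#' Adjacency-constrained Ward clustering of a band similarity
#'
#' The main algorithm: hierarchical agglomerative clustering in which only
#' clusters adjacent in the object ordering may merge, with Ward's linkage
#' evaluated from the similarity.  Pencil sums are precomputed once in
#' O(ph); candidate fusions between adjacent clusters are held in a binary
#' min-heap with lazy invalidation.  Each of the \code{p - 1} merge steps
#' pops the best active fusion, invalidates its (up to two) neighbour
#' fusions, and computes and inserts the (up to two) new candidate fusions
#' in O(1) each -- at the chromosome ends only one new fusion is defined.
#' Total time O(p(h + log p)), memory O(ph).
#'
#' Ties in linkage are broken towards the fusion with the smaller
#' left-boundary index, so the output is deterministic.  Heights are
#' recorded as raw Ward linkages; a warning is emitted when any height is
#' negative (possible for general, non-positive-semidefinite similarities
#' -- the hierarchy itself is unaffected, by the diagonal-shift invariance).
#'
#' @param B a [BandSimilarity-class] with \code{p >= 2}.
#' @return A [Dendrogram-class].
#' @examples
#' B <- bandFromDense(diag(4) + 0.5, h = 4)
#' D <- bandClust(B)
#' cutClusters(D, 2)
#' @seealso [naiveClust()] for the quadratic reference implementation.
#' @export
bandClust <- function(B) {
  stopifnot(is(B, "BandSimilarity"))
  p <- B@p
  if (p < 2L) stopf("need at least 2 objects to cluster")
  P <- pencilSums(B)
  res <- .cpp_band_hac(P@fwd, P@bwd, P@full, p, B@h)
  mg <- res$merges
  colnames(mg) <- c("leftRef", "rightRef", "i", "m", "j",
                    "height", "sizeLeft", "sizeRight")
  if (res$discards > 2L * p)
    warnf("heap cleaning removed %d stale roots (> 2p)", res$discards)
  if (any(mg[, "height"] < 0))
    warnf("%d negative merge heights (general similarity; hierarchy unaffected)",
          sum(mg[, "height"] < 0))
  D <- newDendrogram(p, mg)
  attr(D, "heapDiscards") <- res$discards
  D
}

#' Quadratic reference: adjacency-constrained Ward clustering, naive form
#'
#' Direct implementation of the textbook constrained HAC: at every step the
#' linkage of every candidate adjacent fusion is recomputed from scratch by
#' summing similarity entries of the dense matrix, and the minimum (ties
#' broken towards the smaller left boundary, as in [bandClust()]) is
#' merged.  Quadratic in time and space; intended as an independent
#' correctness reference for small problems.
#'
#' @param M dense symmetric similarity matrix (p >= 2).
#' @return A [Dendrogram-class].
#' @export
naiveClust <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stopf("'M' must be square")
  p <- nrow(M)
  if (p < 2L) stopf("need at least 2 objects to cluster")
  M <- (M + t(M)) / 2
  SC <- function(i, j) sum(M[i:(j - 1L), i:(j - 1L)])
  delta <- function(i, m, j)
    SC(i, m) / (m - i) + SC(m, j) / (j - m) - SC(i, j) / (j - i)

  starts <- seq_len(p)              # left boundary of each current cluster
  ends <- 2:(p + 1L)
  clusterStep <- integer(p)
  mg <- matrix(0, p - 1L, 8L,
               dimnames = list(NULL, c("leftRef", "rightRef", "i", "m", "j",
                                       "height", "sizeLeft", "sizeRight")))
  for (step in seq_len(p - 1L)) {
    nc <- length(starts)
    link <- vapply(seq_len(nc - 1L), function(t)
      delta(starts[t], starts[t + 1L], ends[t + 1L]), numeric(1))
    best <- which.min(link)         # first minimum = leftmost tie-break
    i <- starts[best]; m <- starts[best + 1L]; j <- ends[best + 1L]
    leftRef <- if (m - i == 1L) -i else clusterStep[i]
    rightRef <- if (j - m == 1L) -m else clusterStep[m]
    mg[step, ] <- c(leftRef, rightRef, i, m, j, link[best], m - i, j - m)
    clusterStep[i] <- step
    starts <- starts[-(best + 1L)]
    ends <- ends[-best]
  }
  if (any(mg[, "height"] < 0))
    warnf("%d negative merge heights (general similarity; hierarchy unaffected)",
          sum(mg[, "height"] < 0))
  newDendrogram(p, mg)
}
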