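#' @include Dendrogram-class.R
NULL

#' ClusterSelection: a chosen number of clusters with its criterion trace
#'
#' Result of a model-selection rule applied to a [Dendrogram-class]: the
#' chosen number of clusters \code{K}, the corresponding contiguous labels,
#' and the per-K criterion values that led to the choice.
#'
#' @slot K chosen number of clusters.
#' @slot labels integer labels, identical to \code{cutClusters(D, K)}.
#' @slot method \code{"broken-stick"} or \code{"slope-heuristic"}.
#' @slot trace data.frame of per-K criterion values (columns depend on the
#'   method: observed dispersion decreases and broken-stick expectations,
#'   or contrast, penalty shape and penalised contrast).
#'
#' @seealso [selectBrokenStick()], [selectSlopeHeuristic()]
#' @export
setClass("ClusterSelection",
  representation(K = "integer", labels = "integer", method = "character",
                 trace = "data.frame"))

#' @describeIn ClusterSelection the chosen number of clusters
#' @param x a \code{ClusterSelection}.
#' @export
#' @name selectedK
setMethod("selectedK", "ClusterSelection", function(x) x@K)

#' Cluster labels of a selection
#' @param x a \code{ClusterSelection}.
#' @return Integer vector of contiguous cluster labels.
#' @export
#' @name clusterLabels
setMethod("clusterLabels", "ClusterSelection", function(x) x@labels)

#' Per-K criterion trace of a selection
#' @param x a \code{ClusterSelection}.
#' @return A data.frame, one row per candidate K.
#' @export
#' @name selectionTrace
setMethod("selectionTrace", "ClusterSelection", function(x) x@trace)

setMethod("show", "ClusterSelection", function(object) {
  cat(sprintf("ClusterSelection (%s): K = %d over %d objects\n",
              object@method, object@K, length(object@labels)))
})

## dispersion decreases from the root: d_k = height of the k-th merge
## counted from the top (the split producing k + 1 clusters)
.rootDecreases <- function(D) rev(mergeHeights(D))

#' Choose K by the broken-stick rule
#'
#' Starting at the root of the dendrogram, the dispersion decrease
#' \eqn{d_k} of the k-th split (the height of the k-th merge from the top)
#' is compared with the expected size \eqn{b_k} of the k-th largest piece
#' of a stick of length \eqn{T = \sum_k d_k} broken uniformly at random
#' into \eqn{p - 1} pieces:
#' \deqn{b_k = \frac{T}{p-1} \sum_{i=k}^{p-1} \frac{1}{i}.}
#' Descent stops at the first split whose decrease is no larger than its
#' broken-stick expectation (\eqn{d_k \le b_k}), returning \eqn{K = k}; if
#' every split beats its expectation, \eqn{K = p}.  The rule is a pragmatic
#' stopping heuristic, not a formal test.
#'
#' @param D a [Dendrogram-class].
#' @return A [ClusterSelection-class] with the full \eqn{(d_k, b_k)} trace.
#' @export
selectBrokenStick <- function(D) {
  p <- nObjects(D)
  d <- .rootDecreases(D)
  if (any(d < 0))
    warnf("negative heights in broken-stick comparison (raw Ward linkages)")
  n <- p - 1L
  Tt <- sum(d)
  b <- (Tt / n) * rev(cumsum(1 / rev(seq_len(n))))
  stopAt <- which(d <= b)
  K <- if (length(stopAt)) stopAt[1L] else p
  new("ClusterSelection", K = as.integer(K),
      labels = as.integer(cutClusters(D, K)),
      method = "broken-stick",
      trace = data.frame(K = seq_len(n), d = d, bstick = b))
}

#' Choose K by the slope heuristic
#'
#' Treats the K-cluster cut as a segmentation model and selects K by
#' penalised contrast.  The contrast is the pseudo-inertia of the
#' K-cluster partition, \eqn{C(K) = T - \sum_{k < K} d_k} (total
#' dispersion minus what the first \eqn{K - 1} splits from the root
#' removed).  The penalty shape is the log-binomial
#' \eqn{\mathrm{pen}(K) = \log {p-1 \choose K-1}}, evaluated through the
#' log-gamma function so it stays finite at genomic p; the constant
#' \eqn{\kappa} is calibrated from the data by a robust (Theil-Sen) fit of
#' \eqn{C(K)} against \eqn{\mathrm{pen}(K)} over the upper half of the
#' search range, where the contrast is expected to decrease linearly in
#' the penalty shape.  The selected K minimises
#' \eqn{C(K) + 2\hat\kappa\,\mathrm{pen}(K)}.
#'
#' @param D a [Dendrogram-class].
#' @param Kmax upper bound of the search range; at least 10 is recommended
#'   for a stable slope fit.
#' @return A [ClusterSelection-class] with the per-K trace.
#' @export
selectSlopeHeuristic <- function(D, Kmax = min(nObjects(D), 20L)) {
  p <- nObjects(D)
  if (Kmax < 2L || Kmax > p) stopf("Kmax must be in [2, %d]", p)
  Kmax <- as.integer(Kmax)
  d <- .rootDecreases(D)
  Tt <- sum(d)
  K <- seq_len(Kmax)
  contrast <- Tt - c(0, cumsum(d))[K]
  pen <- lchoose(p - 1, K - 1)
  ## Theil-Sen slope of contrast vs pen over the upper half of the range
  win <- K >= ceiling(Kmax / 2)
  x <- pen[win]; y <- contrast[win]
  pairs <- which(outer(x, x, "!=") & upper.tri(matrix(0, length(x), length(x))),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    stopf("degenerate slope fit: penalty shape constant over the window")
  slopes <- (y[pairs[, 2L]] - y[pairs[, 1L]]) / (x[pairs[, 2L]] - x[pairs[, 1L]])
  kappa <- max(0, -median(slopes))
  crit <- contrast + 2 * kappa * pen
  Ksel <- K[which.min(crit)]
  new("ClusterSelection", K = as.integer(Ksel),
      labels = as.integer(cutClusters(D, Ksel)),
      method = "slope-heuristic",
      trace = data.frame(K = K, contrast = contrast, pen = pen,
                         penalized = crit))
}

#' Write a selection trace to TSV
#'
#' The per-K criterion table plus a header comment with the chosen K.
#'
#' @param sel a [ClusterSelection-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeSelectionTrace <- function(sel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s selected_K=%d", sel@method, sel@K), con)
  write.table(sel@trace, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
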