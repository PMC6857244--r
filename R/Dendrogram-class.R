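#' @include PencilSums-class.R
NULL

#' Dendrogram: the recorded merge history of a constrained clustering
#'
#' The \code{p - 1} merges of an adjacency-constrained hierarchical
#' clustering.  Every cluster is a contiguous interval of the ordered
#' objects, so each merge is fully described by three boundaries
#' \code{(i, m, j)}: left cluster \code{[i, m)}, right cluster
#' \code{[m, j)}.  Heights are the raw Ward linkage values; with general
#' (non-positive-semidefinite) similarities they may be non-monotone
#' ("reversals"), which the \code{monotone} flag records.
#'
#' @slot p number of leaves.
#' @slot merges numeric \code{(p-1) x 8} matrix with columns \code{leftRef},
#'   \code{rightRef} (negative = leaf index, positive = earlier step, the
#'   standard agglomerative merge-table convention), \code{i}, \code{m},
#'   \code{j}, \code{height}, \code{sizeLeft}, \code{sizeRight}.
#' @slot monotone \code{TRUE} iff heights are nondecreasing.
#'
#' @seealso [bandClust()], [naiveClust()], [cutClusters()],
#'   [firstDifferenceIndex()]
#' @export
setClass("Dendrogram",
  representation(p = "integer", merges = "matrix", monotone = "logical"))

setValidity("Dendrogram", function(object) {
  p <- object@p
  if (p < 2L) return("need p >= 2 leaves")
  m <- object@merges
  if (nrow(m) != p - 1L) return("need exactly p - 1 merges")
  need <- c("leftRef", "rightRef", "i", "m", "j", "height",
            "sizeLeft", "sizeRight")
  if (!identical(colnames(m), need))
    return(paste("merge columns must be", paste(need, collapse = ", ")))
  if (any(m[, "i"] >= m[, "m"]) || any(m[, "m"] >= m[, "j"]))
    return("merge boundaries must satisfy i < m < j")
  last <- m[p - 1L, ]
  if (last[["i"]] != 1 || last[["j"]] != p + 1)
    return("final merge must cover [1, p+1)")
  TRUE
})

newDendrogram <- function(p, merges) {
  heights <- merges[, "height"]
  new("Dendrogram", p = as.integer(p), merges = merges,
      monotone = !is.unsorted(heights))
}

#' @describeIn Dendrogram number of leaves
#' @param x a \code{Dendrogram}.
#' @export
setMethod("nObjects", "Dendrogram", function(x) x@p)

#' Merge table of a dendrogram
#' @param x a \code{Dendrogram}.
#' @return The \code{(p-1) x 8} merge matrix (see [Dendrogram-class]).
#' @export
#' @name merges
setMethod("merges", "Dendrogram", function(x) x@merges)

#' Merge heights
#' @param x a \code{Dendrogram}.
#' @return Numeric vector of the p - 1 Ward linkage heights, in merge order.
#' @export
#' @name mergeHeights
setMethod("mergeHeights", "Dendrogram", function(x) unname(x@merges[, "height"]))

#' Are the merge heights monotone?
#' @param x a \code{Dendrogram}.
#' @return \code{TRUE} iff heights are nondecreasing (no reversals).
#' @export
#' @name isMonotone
setMethod("isMonotone", "Dendrogram", function(x) x@monotone)

setMethod("show", "Dendrogram", function(object) {
  h <- mergeHeights(object)
  cat(sprintf("Dendrogram: %d leaves, %d merges, heights in [%.4g, %.4g]%s\n",
              object@p, nrow(object@merges), min(h), max(h),
              if (object@monotone) "" else " (non-monotone: reversals present)"))
})

#' Cut a dendrogram into K contiguous clusters
#'
#' Undoes the last \code{K - 1} merges: the boundaries removed by the first
#' \code{p - K} merges are applied, leaving \code{K} contiguous blocks
#' labelled \code{1..K} from left to right.
#'
#' @param x a \code{Dendrogram}.
#' @param K number of clusters, \code{1 <= K <= p}.
#' @return Integer vector of length \code{p} of cluster labels.
#' @export
#' @name cutClusters
setMethod("cutClusters", "Dendrogram", function(x, K) {
  p <- x@p
  if (length(K) != 1L || is.na(K) || K < 1 || K > p)
    stopf("K must be in [1, %d]", p)
  K <- as.integer(K)
  used <- x@merges[seq_len(p - K), "m"]
  bnd <- sort(setdiff(2:p, used))
  findInterval(seq_len(p), c(1, bnd))
})

#' First-difference index between two dendrograms
#'
#' The fraction \eqn{t/(p-1)} where \eqn{t} is the number of leading merge
#' steps on which the two dendrograms perform the same fusion (same left and
#' right intervals; heights are ignored).  Ranges from 0 (the very first
#' fusions differ) to 1 (identical hierarchies).  Used to quantify the
#' quality of the band approximation and to choose a bandwidth.
#'
#' @param D1,D2 [Dendrogram-class] objects over the same number of leaves.
#' @return A value in \code{[0, 1]}.
#' @export
firstDifferenceIndex <- function(D1, D2) {
  stopifnot(is(D1, "Dendrogram"), is(D2, "Dendrogram"))
  if (D1@p != D2@p) stopf("dendrograms have different numbers of leaves")
  same <- D1@merges[, "i"] == D2@merges[, "i"] &
    D1@merges[, "m"] == D2@merges[, "m"] &
    D1@merges[, "j"] == D2@merges[, "j"]
  t <- if (all(same)) length(same) else which.min(same) - 1L
  t / (D1@p - 1)
}

## ---- interop and I/O --------------------------------------------------

#' Convert a Dendrogram to a stats::hclust object
#'
#' Leaf order is the identity (the adjacency constraint keeps leaves in
#' genomic order).  Heights are the raw Ward linkages; base plotting may
#' warn when these are non-monotone.
#'
#' @param x a \code{Dendrogram}.
#' @param ... ignored.
#' @return An object of class \code{"hclust"}.
#' @export
as.hclust.Dendrogram <- function(x, ...) {
  structure(list(
    merge = cbind(as.integer(x@merges[, "leftRef"]),
                  as.integer(x@merges[, "rightRef"])),
    height = x@merges[, "height"],
    order = seq_len(x@p),
    labels = as.character(seq_len(x@p)),
    method = "ward (adjacency-constrained)",
    call = match.call(),
    dist.method = "band similarity"), class = "hclust")
}

#' Export a dendrogram as a Newick string or file
#'
#' Negative heights (possible with general similarities) are clamped at 0
#' with a warning before branch lengths are derived.
#'
#' @param D a \code{Dendrogram}.
#' @param file optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to file.
#' @export
dendrogramToNewick <- function(D, file = NULL) {
  h <- mergeHeights(D)
  if (any(h < 0)) {
    warnf("%d negative heights clamped to 0 for Newick export", sum(h < 0))
    D@merges[, "height"] <- pmax(h, 0)
  }
  if (!D@monotone)
    ## cumulative maximum keeps branch lengths nonnegative under reversals
    D@merges[, "height"] <- cummax(D@merges[, "height"])
  phy <- ape::as.phylo(as.hclust.Dendrogram(D))
  txt <- ape::write.tree(phy, file = "")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Write / read a dendrogram merge table (TSV)
#'
#' Plain-text round trip of the merge history: columns \code{step},
#' \code{left_ref}, \code{right_ref}, \code{height}, \code{size} (merged
#' cluster size).  Interval boundaries are reconstructed from the
#' references on read.
#'
#' @param D a \code{Dendrogram}.
#' @param file path to a TSV file.
#' @return \code{readMergeTable} returns a [Dendrogram-class].
#' @export
writeMergeTable <- function(D, file) {
  m <- D@merges
  tab <- data.frame(step = seq_len(nrow(m)),
                    left_ref = as.integer(m[, "leftRef"]),
                    right_ref = as.integer(m[, "rightRef"]),
                    height = m[, "height"],
                    size = as.integer(m[, "sizeLeft"] + m[, "sizeRight"]))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMergeTable
#' @export
readMergeTable <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t")
  nsteps <- nrow(tab)
  p <- nsteps + 1L
  ival <- matrix(0L, nsteps, 2L)     # [i, j) of the cluster made at each step
  m <- matrix(0, nsteps, 8L,
              dimnames = list(NULL, c("leftRef", "rightRef", "i", "m", "j",
                                      "height", "sizeLeft", "sizeRight")))
  refIval <- function(ref, s) {
    if (ref < 0) c(-ref, -ref + 1L) else ival[ref, ]
  }
  for (s in seq_len(nsteps)) {
    L <- refIval(tab$left_ref[s], s); R <- refIval(tab$right_ref[s], s)
    if (L[2] != R[1]) stopf("merge table row %d is not adjacency-consistent", s)
    ival[s, ] <- c(L[1], R[2])
    m[s, ] <- c(tab$left_ref[s], tab$right_ref[s], L[1], L[2], R[2],
                tab$height[s], L[2] - L[1], R[2] - R[1])
  }
  newDendrogram(p, m)
}
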