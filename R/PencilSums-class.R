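#' @include BandSimilarity-class.R
NULL

#' PencilSums: precomputed pencil cumulative sums
#'
#' Forward and backward "pencil" sums over a [BandSimilarity-class].  The
#' forward pencil \eqn{P(r, l)} is the sum of all \eqn{s_{ab}} with
#' \eqn{1 \le a, b \le r} and \eqn{|a - b| < l} (the first \eqn{l}
#' sub/superdiagonals of the leading \eqn{r \times r} block); the backward
#' pencil is its mirror over the trailing block.  Both tables are filled by
#' one-pass cumulative-sum recursions in \eqn{O(ph)} time and space, after
#' which the similarity mass \eqn{S(C)} of any contiguous cluster -- and
#' hence any Ward linkage between adjacent clusters -- is available in
#' constant time.
#'
#' Index convention: the forward pencil at boundary \eqn{b} covers indices
#' \eqn{\le b} and the backward pencil at \eqn{i} covers indices
#' \eqn{\ge i}, so that for \eqn{C = \{i, \dots, j-1\}} of size
#' \eqn{k = j - i} and \eqn{l = \min(h, k)}:
#' \deqn{S(C) = P(j-1, l) + \bar{P}(i, l) - P(p, l).}
#'
#' @slot p,h copied from the source similarity.
#' @slot fwd numeric \code{(p+1) x h}; row \code{r+1} holds \eqn{P(r, l)}
#'   for \eqn{r = 0, \dots, p}.
#' @slot bwd numeric \code{(p+1) x h}; row \code{r} holds \eqn{\bar P(r, l)}
#'   for \eqn{r = 1, \dots, p+1} (row \code{p+1} is zero).
#' @slot full numeric length-\code{h}; \eqn{P(p, l)} for each \eqn{l}.
#'
#' @seealso [pencilSums()], [intervalSum()], [wardLinkage()]
#' @export
setClass("PencilSums",
  representation(p = "integer", h = "integer", fwd = "matrix",
                 bwd = "matrix", full = "numeric"))

setValidity("PencilSums", function(object) {
  p <- object@p; h <- object@h
  if (!identical(dim(object@fwd), c(p + 1L, h))) return("'fwd' must be (p+1) x h")
  if (!identical(dim(object@bwd), c(p + 1L, h))) return("'bwd' must be (p+1) x h")
  if (length(object@full) != h) return("'full' must have length h")
  if (any(object@fwd[1L, ] != 0)) return("P(0, l) must be 0")
  if (any(object@bwd[p + 1L, ] != 0)) return("Pbar(p+1, l) must be 0")
  TRUE
})

setMethod("nObjects", "PencilSums", function(x) x@p)
setMethod("bandwidth", "PencilSums", function(x) x@h)

setMethod("show", "PencilSums", function(object) {
  cat(sprintf("PencilSums: p = %d, h = %d (%d stored pencils <= 2ph = %d)\n",
              object@p, object@h, 2L * object@p * object@h,
              2L * object@p * object@h))
})

#' Precompute pencil sums
#'
#' Fills the forward and backward pencil tables of a band similarity by
#' cumulative-sum recursions; total work and storage are proportional to
#' \code{p * h} (at most \code{2ph} stored pencils), with no quadratic term.
#'
#' @param B a [BandSimilarity-class].
#' @return A [PencilSums-class] object.
#' @examples
#' B <- bandFromDense(matrix(1, 3, 3), h = 3)
#' P <- pencilSums(B)
#' intervalSum(P, 1, 3)  # sum over the 2x2 leading block = 4
#' @export
pencilSums <- function(B) {
  stopifnot(is(B, "BandSimilarity"))
  p <- B@p; h <- B@h
  ## forward table, plus the forward table of the reversed ordering with its
  ## rows flipped back (= the backward table), filled in one C++ pass
  tabs <- .cpp_pencil_tables(B@band)
  new("PencilSums", p = p, h = h, fwd = tabs$fwd, bwd = tabs$bwd,
      full = tabs$fwd[p + 1L, ])
}

#' Interval similarity sum S(C)
#'
#' Sum of all similarities \eqn{s_{ab}} over \eqn{(a, b) \in C^2} for the
#' contiguous cluster \eqn{C = \{i, \dots, j-1\}} (half-open \code{[i, j)}),
#' evaluated in O(1) from the pencil tables.  Vectorised over \code{i, j}.
#'
#' @param P a [PencilSums-class].
#' @param i,j interval bounds, \code{1 <= i < j <= p + 1}.
#' @return Numeric vector of interval sums.
#' @export
intervalSum <- function(P, i, j) {
  if (any(i < 1L) || any(j > P@p + 1L) || any(i >= j))
    stopf("interval must satisfy 1 <= i < j <= p + 1")
  l <- pmin(P@h, j - i)
  P@fwd[cbind(j, l)] + P@bwd[cbind(i, l)] - P@full[l]
}

#' Ward linkage between adjacent contiguous clusters
#'
#' Ward's linkage \eqn{\delta(C, C')} between the adjacent clusters
#' \eqn{C = [i, m)} and \eqn{C' = [m, j)}, computed in O(1) from three
#' interval sums via the similarity ("kernel trick") form
#' \deqn{\delta(C, C') = S(C)/|C| + S(C')/|C'| - S(C \cup C')/|C \cup C'|,}
#' which for inner-product similarities equals the classical increase in
#' error sum of squares caused by the merge.  Vectorised over
#' \code{i, m, j}.
#'
#' @param P a [PencilSums-class].
#' @param i,m,j boundaries with \code{1 <= i < m < j <= p + 1}.
#' @return Numeric vector of linkage values (may be negative for general,
#'   non-positive-semidefinite similarities).
#' @export
wardLinkage <- function(P, i, m, j) {
  if (any(i >= m) || any(m >= j))
    stopf("need 1 <= i < m < j <= p + 1")
  intervalSum(P, i, m) / (m - i) + intervalSum(P, m, j) / (j - m) -
    intervalSum(P, i, j) / (j - i)
}
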