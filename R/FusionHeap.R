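#' @include utils.R
NULL

## Binary min-heap of candidate fusions with lazy invalidation.
##
## The heap proper stores only (linkage, tiebreak key, id) triples; all
## mutable state -- the active/inactive flag of each candidate fusion --
## lives in a side array addressed by id.  Invalidation flips the flag in
## O(1) without touching the heap array; stale entries are discarded when
## they surface at the root ("root cleaning"), which over a full clustering
## run deletes at most 2p roots.
##
## Reference semantics via an environment: the engine mutates one shared
## heap across p - 1 merge steps.

#' Create an empty fusion heap
#'
#' A binary min-heap over candidate adjacent-cluster fusions, ordered by
#' \code{(linkage, key)} lexicographically -- among equal linkages the
#' fusion with the smaller tiebreak key (left-boundary index) wins, making
#' clustering output deterministic.  Invalidated fusions are removed lazily
#' when they reach the root.
#'
#' @param capacity initial storage (grown automatically).
#' @return An environment of class \code{"FusionHeap"}.
#' @seealso [heapInsert()], [heapInvalidate()], [heapPopMinActive()]
#' @export
newFusionHeap <- function(capacity = 64L) {
  H <- new.env(parent = emptyenv())
  H$link <- numeric(capacity)
  H$key <- numeric(capacity)
  H$id <- integer(capacity)
  H$n <- 0L
  H$valid <- logical(0)       # side array, indexed by id; NA = unknown id
  H$discards <- 0L            # lazily deleted (stale) roots
  class(H) <- "FusionHeap"
  H
}

#' @export
print.FusionHeap <- function(x, ...) {
  cat(sprintf("FusionHeap: %d stored entries, %d active, %d lazy discards\n",
              x$n, sum(x$valid, na.rm = TRUE), x$discards))
  invisible(x)
}

## (a) strictly less than (b) in (linkage, key) lexicographic order
.heapLess <- function(H, a, b) {
  H$link[a] < H$link[b] || (H$link[a] == H$link[b] && H$key[a] < H$key[b])
}

.heapSwap <- function(H, a, b) {
  tl <- H$link[a]; H$link[a] <- H$link[b]; H$link[b] <- tl
  tk <- H$key[a]; H$key[a] <- H$key[b]; H$key[b] <- tk
  ti <- H$id[a]; H$id[a] <- H$id[b]; H$id[b] <- ti
}

#' Insert a candidate fusion
#'
#' Pushes \code{(linkage, key, id)} in O(log n).  The id must be fresh
#' (never inserted before); it is registered as active in the side array.
#'
#' @param H a [newFusionHeap()] heap.
#' @param id unique positive integer identifier.
#' @param linkage Ward linkage value of the candidate fusion.
#' @param key tiebreak key (left-boundary index of the fusion).
#' @return \code{H}, invisibly.
#' @export
heapInsert <- function(H, id, linkage, key) {
  id <- as.integer(id)
  if (id < 1L) stopf("fusion id must be a positive integer")
  if (id <= length(H$valid) && !is.na(H$valid[id]))
    stopf("fusion id %d already known to the heap", id)
  if (id > length(H$valid)) {
    grown <- rep(NA, max(id, 2L * length(H$valid)))
    grown[seq_along(H$valid)] <- H$valid
    H$valid <- grown
  }
  H$valid[id] <- TRUE
  n <- H$n + 1L
  if (n > length(H$id)) {
    newcap <- 2L * length(H$id)
    length(H$link) <- newcap; length(H$key) <- newcap; length(H$id) <- newcap
  }
  H$link[n] <- linkage; H$key[n] <- key; H$id[n] <- id
  H$n <- n
  ## sift up
  while (n > 1L) {
    par <- n %/% 2L
    if (.heapLess(H, n, par)) { .heapSwap(H, n, par); n <- par } else break
  }
  invisible(H)
}

#' Build a fusion heap from vectors of candidates
#'
#' @param ids integer identifiers (must be distinct).
#' @param linkages,keys parallel numeric vectors.
#' @return A \code{FusionHeap}.
#' @export
heapBuild <- function(ids, linkages, keys = seq_along(ids)) {
  if (anyDuplicated(ids)) stopf("duplicate fusion ids")
  H <- newFusionHeap(max(2L * length(ids), 8L))
  for (t in seq_along(ids)) heapInsert(H, ids[t], linkages[t], keys[t])
  H
}

#' Invalidate a candidate fusion
#'
#' Flips the fusion's active flag in the side array in O(1); the heap array
#' is untouched and the stale entry is discarded lazily at the root.
#'
#' @param H a \code{FusionHeap}.
#' @param id identifier of a known fusion.
#' @return \code{H}, invisibly.
#' @export
heapInvalidate <- function(H, id) {
  if (id < 1L || id > length(H$valid) || is.na(H$valid[id]))
    stopf("unknown fusion id %s", id)
  H$valid[id] <- FALSE
  invisible(H)
}

## remove the root and restore heap order
.heapPopRoot <- function(H) {
  n <- H$n
  H$link[1L] <- H$link[n]; H$key[1L] <- H$key[n]; H$id[1L] <- H$id[n]
  H$n <- n <- n - 1L
  k <- 1L
  repeat {
    l <- 2L * k; r <- l + 1L
    if (l > n) break
    m <- if (r <= n && .heapLess(H, r, l)) r else l
    if (.heapLess(H, m, k)) { .heapSwap(H, k, m); k <- m } else break
  }
}

#' Pop the minimum active fusion
#'
#' Cleans the heap by discarding inactive roots, then removes and returns
#' the active fusion with the smallest \code{(linkage, key)}.  Returns
#' \code{NULL} when no active fusion remains (the "empty of active
#' fusions" signal).
#'
#' @param H a \code{FusionHeap}.
#' @return \code{list(id=, linkage=, key=)} or \code{NULL}.
#' @export
heapPopMinActive <- function(H) {
  while (H$n > 0L && !H$valid[H$id[1L]]) {
    .heapPopRoot(H)
    H$discards <- H$discards + 1L
  }
  if (H$n == 0L) return(NULL)
  out <- list(id = H$id[1L], linkage = H$link[1L], key = H$key[1L])
  H$valid[out$id] <- FALSE      # popped = consumed
  .heapPopRoot(H)
  out
}

#' Number of active fusions in a heap
#' @param H a \code{FusionHeap}.
#' @return Integer count.
#' @export
heapActiveCount <- function(H) sum(H$valid, na.rm = TRUE)

#' Lazy-deletion counter
#' @param H a \code{FusionHeap}.
#' @return Number of stale roots discarded so far.
#' @export
heapDiscards <- function(H) H$discards
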