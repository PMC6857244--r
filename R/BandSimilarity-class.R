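#' @include AllGenerics.R
NULL

#' BandSimilarity: a symmetric similarity stored as its first h diagonals
#'
#' A symmetric similarity matrix over \code{p} ordered objects under the band
#' assumption: \eqn{s_{ij} = 0} whenever \eqn{|i - j| \ge h}.  Only the main
#' diagonal and the \code{h - 1} superdiagonals are stored, in a \code{p x h}
#' matrix whose entry \code{(i, d + 1)} holds \eqn{s_{i, i+d}} for
#' \eqn{0 \le d < h} (entries running past column \code{p} are zero-padded).
#' Symmetric completion is implied: querying \eqn{s_{ij}} with \eqn{j < i}
#' returns \eqn{s_{ji}}, and any pair with \eqn{|i - j| \ge h} returns
#' exactly 0.
#'
#' @slot p integer, number of ordered objects.
#' @slot h integer bandwidth, \code{1 <= h <= p}.
#' @slot band numeric \code{p x h} matrix of in-band similarities.
#' @slot labels optional character vector of object names.
#' @slot positions optional numeric vector of genomic coordinates (bp).
#'
#' @seealso [bandFromDense()], [bandFromTriplets()], [bandFromDissimilarity()],
#'   [bandClust()]
#' @export
setClass("BandSimilarity",
  representation(p = "integer", h = "integer", band = "matrix",
                 labels = "character", positions = "numeric"),
  prototype(labels = character(0), positions = numeric(0))
)

setValidity("BandSimilarity", function(object) {
  p <- object@p; h <- object@h
  if (length(p) != 1L || is.na(p) || p < 1L) return("'p' must be a single positive integer")
  if (length(h) != 1L || is.na(h) || h < 1L || h > p)
    return("'h' must satisfy 1 <= h <= p")
  if (!is.numeric(object@band) || nrow(object@band) != p || ncol(object@band) != h)
    return("'band' must be a numeric p x h matrix")
  if (!all(is.finite(object@band)))
    return("all stored similarities must be finite")
  if (h > 1L) {
    ## zero padding beyond position p
    for (d in seq_len(h - 1L)) {
      idx <- seq.int(p - d + 1L, p)
      if (any(object@band[idx, d + 1L] != 0))
        return("band entries past the matrix edge must be zero")
    }
  }
  if (length(object@labels) && length(object@labels) != p)
    return("'labels' must have length p")
  if (length(object@positions) && length(object@positions) != p)
    return("'positions' must have length p")
  TRUE
})

#' @describeIn BandSimilarity number of objects
#' @param x a \code{BandSimilarity}.
#' @export
setMethod("nObjects", "BandSimilarity", function(x) x@p)

#' @describeIn BandSimilarity bandwidth h
#' @export
setMethod("bandwidth", "BandSimilarity", function(x) x@h)

#' Raw band value matrix
#'
#' The \code{p x h} matrix holding \eqn{s_{i,i+d}} at entry \code{(i, d+1)}.
#'
#' @param x a \code{BandSimilarity}.
#' @return A numeric matrix.
#' @export
#' @name bandValues
setMethod("bandValues", "BandSimilarity", function(x) x@band)

#' Object labels
#'
#' Optional per-object names (e.g. SNP identifiers).
#'
#' @param x an object with per-locus labels.
#' @return Character vector (possibly empty).
#' @export
#' @name objectLabels
setMethod("objectLabels", "BandSimilarity", function(x) x@labels)

#' Genomic positions
#'
#' Optional per-object genomic coordinates, in base pairs.
#'
#' @param x an object with per-locus positions.
#' @return Numeric vector (possibly empty).
#' @export
#' @name objectPositions
setMethod("objectPositions", "BandSimilarity", function(x) x@positions)

setMethod("show", "BandSimilarity", function(object) {
  cat(sprintf("BandSimilarity: %d objects, bandwidth h = %d (%.1f%% of full)\n",
              object@p, object@h, 100 * object@h / object@p))
  cat(sprintf("  stored values: %d; range [%.4g, %.4g]\n",
              length(object@band), min(object@band), max(object@band)))
  if (length(object@labels))
    cat("  labels: ", paste(head(object@labels, 3L), collapse = ", "),
        if (object@p > 3L) ", ..." else "", "\n", sep = "")
})

## ---- constructors -----------------------------------------------------

newBandSimilarity <- function(band, labels = character(0),
                              positions = numeric(0)) {
  new("BandSimilarity", p = nrow(band), h = ncol(band),
      band = band, labels = labels,
      positions = as.numeric(positions))
}

checkBandwidthArg <- function(h, p) {
  if (length(h) != 1L || !is.finite(h) || h < 1 || h > p)
    stopf("bandwidth h must satisfy 1 <= h <= p = %d (got %s)", p,
          paste(h, collapse = ","))
  as.integer(h)
}

#' Build a BandSimilarity from a dense symmetric matrix
#'
#' Keeps the first \code{h} diagonals of \code{M}.  Out-of-band entries are
#' either required to be zero (\code{strict = TRUE}) or silently dropped.
#'
#' @param M square numeric matrix, symmetric to within \code{1e-8} absolute.
#' @param h bandwidth; \code{h = nrow(M)} keeps everything.
#' @param strict if \code{TRUE}, any nonzero entry with \code{|i - j| >= h}
#'   is an error rather than being dropped.
#' @param labels,positions optional per-object annotation.
#' @return A [BandSimilarity-class] object.
#' @examples
#' B <- bandFromDense(diag(3), h = 1)
#' bandToDense(B)
#' @export
bandFromDense <- function(M, h = nrow(M), strict = FALSE,
                          labels = character(0), positions = numeric(0)) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stopf("'M' must be a square matrix")
  if (!all(is.finite(M))) stopf("'M' has non-finite entries")
  p <- nrow(M)
  h <- checkBandwidthArg(h, p)
  if (max(abs(M - t(M))) > 1e-8)
    stopf("'M' is not symmetric (max |M - t(M)| = %g > 1e-8)",
          max(abs(M - t(M))))
  M <- (M + t(M)) / 2
  if (strict && h < p) {
    out <- abs(row(M) - col(M)) >= h
    if (any(M[out] != 0))
      stopf("strict band violation: %d nonzero entries with |i-j| >= h",
            sum(M[out] != 0) / 2)
  }
  band <- matrix(0, p, h)
  for (d in 0:(h - 1L)) {
    i <- seq_len(p - d)
    band[i, d + 1L] <- M[cbind(i, i + d)]
  }
  if (is.null(labels) || !length(labels))
    labels <- if (!is.null(rownames(M))) rownames(M) else character(0)
  newBandSimilarity(band, labels = labels, positions = positions)
}

#' Build a BandSimilarity from (i, j, value) triplets
#'
#' Sparse construction in the MatrixMarket spirit: indices are 1-based, and
#' either one or both of \code{(i, j)} and \code{(j, i)} may be given (values
#' must agree when both are).  Unspecified in-band entries default to 0;
#' missing diagonal entries default to 0 with a warning (self-similarities
#' are often omitted from Hi-C maps).
#'
#' @param i,j integer vectors of 1-based indices.
#' @param x numeric values.
#' @param p number of objects.
#' @param h bandwidth; triplets with \code{|i - j| >= h} are dropped.
#' @param labels,positions optional per-object annotation.
#' @return A [BandSimilarity-class] object.
#' @export
bandFromTriplets <- function(i, j, x, p, h,
                             labels = character(0), positions = numeric(0)) {
  p <- as.integer(p)
  h <- checkBandwidthArg(h, p)
  i <- as.integer(i); j <- as.integer(j); x <- as.numeric(x)
  if (length(i) != length(j) || length(i) != length(x))
    stopf("'i', 'j', 'x' must have equal length")
  if (length(i) && (min(i, j) < 1L || max(i, j) > p))
    stopf("triplet indices out of range [1, %d]", p)
  if (!all(is.finite(x))) stopf("non-finite triplet values")
  ## canonical upper-triangle orientation
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    split_x <- split(x, key)
    bad <- vapply(split_x, function(v) max(v) - min(v) > 1e-12, logical(1))
    if (any(bad))
      stopf("conflicting duplicate triplets for %d pair(s)", sum(bad))
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]; x <- x[keep]
  }
  inband <- (hi - lo) < h
  band <- matrix(0, p, h)
  if (any(inband))
    band[cbind(lo[inband], hi[inband] - lo[inband] + 1L)] <- x[inband]
  if (!all(seq_len(p) %in% lo[hi == lo]))
    warnf("%d diagonal entries absent from triplets; set to 0",
          p - sum(seq_len(p) %in% lo[hi == lo]))
  newBandSimilarity(band, labels = labels, positions = positions)
}

#' Build a (full-bandwidth) BandSimilarity from a dissimilarity matrix
#'
#' Converts pairwise dissimilarities to similarities via
#' \eqn{s_{ij} = (c - d_{ij}^2)/2} with \eqn{c = \max_{ij} d_{ij}^2}.  The
#' resulting Ward hierarchy is invariant to the choice of the additive
#' constant \eqn{c}, because a uniform shift of all entries leaves every
#' linkage value unchanged.  Only \code{h = p} is supported: out-of-band
#' pairs are hard-coded to similarity 0, which is incompatible with the
#' additive constant.
#'
#' @param D square symmetric nonnegative matrix (or \code{dist}) with zero
#'   diagonal.
#' @param labels,positions optional per-object annotation.
#' @return A [BandSimilarity-class] object with \code{h = p}.
#' @export
bandFromDissimilarity <- function(D, labels = character(0),
                                  positions = numeric(0)) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stopf("'D' must be square")
  if (any(D < 0)) stopf("dissimilarities must be nonnegative")
  if (any(diag(D) != 0)) stopf("dissimilarity diagonal must be zero")
  if (max(abs(D - t(D))) > 1e-8) stopf("'D' is not symmetric")
  D2 <- ((D + t(D)) / 2)^2
  S <- (max(D2) - D2) / 2
  bandFromDense(S, h = nrow(D), labels = labels, positions = positions)
}

#' Shift the diagonal of a band similarity
#'
#' Replaces \eqn{s_{ii}} by \eqn{s_{ii} + \lambda} for all \code{i}, leaving
#' off-diagonal entries untouched.  By Miyamoto's result this yields the
#' exact same Ward hierarchy, with every linkage value shifted by
#' \eqn{+\lambda} -- which justifies applying the similarity form of Ward's
#' linkage to general (possibly non-positive-definite) similarity matrices.
#'
#' @param x a \code{BandSimilarity}.
#' @param lambda finite numeric shift.
#' @return A shifted \code{BandSimilarity}.
#' @export
#' @name shiftDiagonal
setMethod("shiftDiagonal", "BandSimilarity", function(x, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda))
    stopf("'lambda' must be a single finite number")
  x@band[, 1L] <- x@band[, 1L] + lambda
  x
})

#' Densify a BandSimilarity
#'
#' Reconstructs the full symmetric \code{p x p} matrix (out-of-band entries
#' are exactly 0).  Intended for small problems and testing.
#'
#' @param B a \code{BandSimilarity}.
#' @return A numeric \code{p x p} matrix.
#' @export
bandToDense <- function(B) {
  stopifnot(is(B, "BandSimilarity"))
  p <- B@p; h <- B@h
  M <- matrix(0, p, p)
  for (d in 0:(h - 1L)) {
    i <- seq_len(p - d)
    M[cbind(i, i + d)] <- B@band[i, d + 1L]
    M[cbind(i + d, i)] <- B@band[i, d + 1L]
  }
  if (length(B@labels)) dimnames(M) <- list(B@labels, B@labels)
  M
}

## ---- file readers -----------------------------------------------------

#' Read a dense similarity matrix from delimited text
#'
#' Reads a TSV/CSV square matrix, with an optional header row and leading
#' label column (auto-detected), and converts it with [bandFromDense()].
#'
#' @param file path to a delimited text file.
#' @param h bandwidth (default: full).
#' @param sep field separator; default whitespace/tab via
#'   \code{read.table}, use \code{","} for CSV.
#' @param ... passed to [bandFromDense()].
#' @return A [BandSimilarity-class] object.
#' @export
readDenseSimilarity <- function(file, h = NULL, sep = "", ...) {
  nf <- utils::count.fields(file, sep = sep)
  if (length(nf) > 1 && nf[1] == nf[2] - 1) {
    ## header row one field short of the data rows: labelled matrix with a
    ## header line and a leading label column
    raw <- read.table(file, sep = sep, header = TRUE, row.names = 1,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    raw <- read.table(file, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE)
    ## header detection: first cell non-numeric
    if (is.character(raw[[1]]) &&
        suppressWarnings(is.na(as.numeric(raw[1, 1])))) {
      raw <- read.table(file, sep = sep, header = TRUE, row.names = 1,
                        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  M <- as.matrix(raw)
  storage.mode(M) <- "double"
  if (is.null(h)) h <- nrow(M)
  bandFromDense(M, h = h, ...)
}

#' Read sparse triplets (MatrixMarket or 3-column TSV)
#'
#' MatrixMarket coordinate files (\code{\%\%MatrixMarket} header) are read with
#' \code{Matrix::readMM}; otherwise the file is parsed as a headerless
#' 3-column \code{i j value} table with 1-based indices.
#'
#' @param file path.
#' @param p number of objects; inferred from the data when \code{NULL}.
#' @param h bandwidth (default: full).
#' @param ... passed to [bandFromTriplets()].
#' @return A [BandSimilarity-class] object.
#' @export
readTripletSimilarity <- function(file, p = NULL, h = NULL, ...) {
  first <- readLines(file, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    M <- Matrix::readMM(file)
    TM <- as(M, "TsparseMatrix")
    i <- TM@i + 1L; j <- TM@j + 1L; x <- TM@x
    if (is.null(p)) p <- nrow(M)
  } else {
    tab <- read.table(file, header = FALSE)
    i <- tab[[1]]; j <- tab[[2]]; x <- tab[[3]]
    if (is.null(p)) p <- max(i, j)
  }
  if (is.null(h)) h <- p
  bandFromTriplets(i, j, x, p = p, h = h, ...)
}
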