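#' @include BandSimilarity-class.R
NULL

#' GenotypeMatrix: allele dosages over ordered SNPs
#'
#' Unphased genotypes for \code{n} individuals at \code{p} SNPs ordered
#' along one chromosome, coded as minor-allele dosages 0/1/2 (\code{NA} =
#' missing).
#'
#' @slot dosages numeric \code{n x p} matrix with values in
#'   \{0, 1, 2, NA\}.
#' @slot snpPositions base-pair coordinates, strictly increasing (may be
#'   empty).
#' @slot chromosome chromosome label.
#' @seealso [ldBand()], [readDosageMatrix()], [readVCFGenotypes()]
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", snpPositions = "numeric",
                 chromosome = "character"),
  prototype(snpPositions = numeric(0), chromosome = "chr?"))

setValidity("GenotypeMatrix", function(object) {
  g <- object@dosages
  if (!is.numeric(g)) return("'dosages' must be numeric")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("dosages must be 0, 1, 2 or NA")
  pos <- object@snpPositions
  if (length(pos)) {
    if (length(pos) != ncol(g)) return("'snpPositions' must match SNP count")
    if (is.unsorted(pos, strictly = TRUE))
      return("'snpPositions' must be strictly increasing")
  }
  TRUE
})

setMethod("nObjects", "GenotypeMatrix", function(x) ncol(x@dosages))
setMethod("objectPositions", "GenotypeMatrix", function(x) x@snpPositions)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%s), %.2f%% missing\n",
              nrow(object@dosages), ncol(object@dosages), object@chromosome,
              100 * mean(is.na(object@dosages))))
})

#' ContactMap: an intra-chromosomal Hi-C contact map
#'
#' Read counts between pairs of genomic bins, stored as sparse triplets.
#'
#' @slot p number of bins.
#' @slot binSize bin width in base pairs.
#' @slot binI,binJ 1-based bin indices of each recorded pair.
#' @slot counts nonnegative integer contact counts.
#' @slot chromosome chromosome label.
#' @seealso [hicBand()], [readContactMap()]
#' @export
setClass("ContactMap",
  representation(p = "integer", binSize = "numeric", binI = "integer",
                 binJ = "integer", counts = "numeric",
                 chromosome = "character"),
  prototype(binSize = 40000, chromosome = "chr?"))

setValidity("ContactMap", function(object) {
  if (length(object@counts) &&
      (any(object@counts < 0) || any(object@counts != round(object@counts))))
    return("counts must be nonnegative integers")
  if (length(object@binI) != length(object@binJ) ||
      length(object@binI) != length(object@counts))
    return("triplet vectors must have equal length")
  if (length(object@binI) &&
      (min(object@binI, object@binJ) < 1L ||
       max(object@binI, object@binJ) > object@p))
    return("bin indices out of range")
  TRUE
})

setMethod("nObjects", "ContactMap", function(x) x@p)

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d bins of %g bp (%s), %d recorded pairs\n",
              object@p, object@binSize, object@chromosome,
              length(object@counts)))
})

## ---- LD adapter -------------------------------------------------------

#' Band similarity from genotypes: linkage-disequilibrium r-squared
#'
#' Builds the LD similarity \eqn{s_{ij} = r^2_{ij}}, the squared Pearson
#' correlation of the allele-dosage vectors of SNPs \code{i} and \code{j}
#' (composite LD, computable without phasing), for all pairs with
#' \eqn{|i - j| < h}.  Missing genotypes are handled pairwise-complete.
#' The diagonal is exactly 1.  Pairs where either SNP is monomorphic (or
#' with no complete observation) get similarity 0; their count is reported
#' in a message.  The \eqn{r^2} similarity is positive semidefinite
#' (a kernel), so all Ward linkages are nonnegative.
#'
#' @param G a [GenotypeMatrix-class] with \code{n >= 2} individuals.
#' @param h bandwidth.
#' @return A [BandSimilarity-class] carrying the SNP positions.
#' @export
ldBand <- function(G, h) {
  stopifnot(is(G, "GenotypeMatrix"))
  g <- G@dosages
  n <- nrow(g); p <- ncol(g)
  if (n < 2L) stopf("need at least 2 individuals")
  if (p < 2L) stopf("need at least 2 SNPs")
  h <- checkBandwidthArg(h, p)
  obs <- !is.na(g)
  if (all(apply(g, 2L, function(x) length(unique(x[!is.na(x)])) <= 1L)))
    stopf("every SNP is monomorphic")
  g0 <- g; g0[!obs] <- 0
  band <- matrix(0, p, h)
  band[, 1L] <- 1
  dropped <- 0L
  for (d in seq_len(h - 1L)) {
    if (d >= p) break
    ii <- seq_len(p - d)
    X <- g0[, ii, drop = FALSE]; Y <- g0[, ii + d, drop = FALSE]
    Mk <- obs[, ii, drop = FALSE] & obs[, ii + d, drop = FALSE]
    np <- colSums(Mk)
    sx <- colSums(X * Mk); sy <- colSums(Y * Mk)
    sxx <- colSums(X * X * Mk); syy <- colSums(Y * Y * Mk)
    sxy <- colSums(X * Y * Mk)
    vx <- np * sxx - sx^2
    vy <- np * syy - sy^2
    cov <- np * sxy - sx * sy
    ok <- np >= 2L & vx > 0 & vy > 0
    r2 <- numeric(length(ii))
    r2[ok] <- (cov[ok]^2) / (vx[ok] * vy[ok])
    dropped <- dropped + sum(!ok)
    band[ii, d + 1L] <- r2
  }
  if (dropped)
    message(sprintf("ldBand: %d SNP pairs monomorphic or without complete observations; r2 set to 0",
                    dropped))
  newBandSimilarity(band, positions = G@snpPositions)
}

## ---- Hi-C adapter -----------------------------------------------------

#' Band similarity from a Hi-C contact map: log counts
#'
#' Contact counts are log-transformed, \eqn{s_{ij} = \log(1 + c_{ij})}, to
#' reduce the skewness of the count distribution; unrecorded pairs keep
#' similarity 0 consistently (\eqn{\log(1 + 0) = 0}).  Pairs beyond the
#' band (\eqn{|i - j| \ge h}) are dropped.
#'
#' @param C a [ContactMap-class].
#' @param h bandwidth.
#' @return A [BandSimilarity-class].
#' @export
hicBand <- function(C, h) {
  stopifnot(is(C, "ContactMap"))
  p <- C@p
  h <- checkBandwidthArg(h, p)
  lo <- pmin(C@binI, C@binJ); hi <- pmax(C@binI, C@binJ)
  keep <- (hi - lo) < h
  band <- matrix(0, p, h)
  if (any(keep))
    band[cbind(lo[keep], hi[keep] - lo[keep] + 1L)] <- log1p(C@counts[keep])
  newBandSimilarity(band)
}

## ---- interval export --------------------------------------------------

.clusterSpans <- function(labels) {
  labels <- as.integer(labels)
  if (is.unsorted(labels) || !identical(sort(unique(labels)),
                                        seq_len(max(labels))))
    stopf("labels must be contiguous blocks numbered 1..K left to right")
  firsts <- match(seq_len(max(labels)), labels)
  lasts <- length(labels) - match(seq_len(max(labels)), rev(labels)) + 1L
  list(first = firsts, last = lasts)
}

#' Contiguous clusters as genomic intervals
#'
#' Converts a contiguous labelling into one interval per cluster, either
#' from per-locus base-pair positions or from a bin size.  GRanges output
#' uses 1-based closed coordinates (Bioconductor convention); BED output is
#' 0-based half-open.  With a bin size the records tile the binned region
#' exactly (no gaps, no overlaps); with SNP positions each record spans the
#' cluster's first to last SNP.
#'
#' @param labels integer labels from [cutClusters()] (contiguous blocks).
#' @param positions per-locus bp coordinates (SNP mode), or \code{NULL}.
#' @param binSize bin width in bp (bin mode), or \code{NULL}.  Exactly one
#'   of \code{positions}/\code{binSize} must be given.
#' @param chromosome chromosome name for the records.
#' @return \code{clustersToGRanges}: a \code{GRanges} with a \code{name}
#'   column; \code{writeClustersBed}: the BED path, invisibly.
#' @export
clustersToGRanges <- function(labels, positions = NULL, binSize = NULL,
                              chromosome = "chr?") {
  if (is.null(positions) == is.null(binSize))
    stopf("give exactly one of 'positions' or 'binSize'")
  sp <- .clusterSpans(labels)
  if (!is.null(binSize)) {
    start1 <- (sp$first - 1L) * binSize + 1
    end1 <- sp$last * binSize
  } else {
    if (length(positions) != length(labels))
      stopf("'positions' must match labels length")
    start1 <- positions[sp$first]
    end1 <- positions[sp$last]
  }
  GenomicRanges::GRanges(
    seqnames = chromosome,
    ranges = IRanges::IRanges(start = start1, end = end1),
    name = sprintf("cluster_%d", seq_along(sp$first)))
}

#' @rdname clustersToGRanges
#' @param file output BED path.
#' @export
writeClustersBed <- function(labels, positions = NULL, binSize = NULL,
                             chromosome = "chr?", file) {
  gr <- clustersToGRanges(labels, positions, binSize, chromosome)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,   # 0-based half-open
                    end = GenomicRanges::end(gr),
                    name = S4Vectors::mcols(gr)$name)
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

## ---- bandwidth selection ----------------------------------------------

#' Data-driven bandwidth selection by dendrogram stability
#'
#' Runs the clustering at increasing bandwidths and returns the first
#' \code{h} whose dendrogram is stable -- its [firstDifferenceIndex()]
#' against the next bandwidth in the schedule reaches the threshold.  For
#' similarities of true bandwidth \eqn{h_0}, results are identical for all
#' \eqn{h \ge h_0}, so the schedule stops there.
#'
#' @param builder function taking a bandwidth and returning a
#'   [BandSimilarity-class] (e.g. \code{function(h) ldBand(G, h)}).
#' @param hSchedule increasing vector of candidate bandwidths (length
#'   >= 2).
#' @param stability threshold in (0, 1]; default 1 (exact stability).
#' @return The selected bandwidth, with the per-step comparison trace
#'   attached as attribute \code{"trace"}.  If the schedule is exhausted
#'   without stabilising, an error carrying the trace (condition attribute
#'   \code{trace}) is signalled.
#' @export
selectBandwidth <- function(builder, hSchedule, stability = 1) {
  if (length(hSchedule) < 2L)
    stopf("'hSchedule' must contain at least 2 bandwidths to compare")
  if (is.unsorted(hSchedule, strictly = TRUE))
    stopf("'hSchedule' must be strictly increasing")
  Dcur <- bandClust(builder(hSchedule[1L]))
  fdi <- numeric(length(hSchedule) - 1L)
  for (t in seq_len(length(hSchedule) - 1L)) {
    Dnext <- bandClust(builder(hSchedule[t + 1L]))
    fdi[t] <- firstDifferenceIndex(Dcur, Dnext)
    if (fdi[t] >= stability) {
      out <- hSchedule[t]
      attr(out, "trace") <- data.frame(h = hSchedule[seq_len(t)],
                                       h_next = hSchedule[seq_len(t) + 1L],
                                       fdi = fdi[seq_len(t)])
      return(out)
    }
    Dcur <- Dnext
  }
  cond <- simpleError("bandwidth schedule exhausted without stabilizing")
  attr(cond, "trace") <- data.frame(h = head(hSchedule, -1L),
                                    h_next = hSchedule[-1L], fdi = fdi)
  stop(cond)
}

## ---- readers -----------------------------------------------------------

#' Read a dosage matrix (individuals x SNPs) from delimited text
#'
#' @param file path; whitespace/TSV numeric table, optional header of SNP
#'   names.  Missing values as NA.
#' @param positions optional bp coordinates.
#' @param chromosome chromosome label.
#' @return A [GenotypeMatrix-class].
#' @export
readDosageMatrix <- function(file, positions = numeric(0),
                             chromosome = "chr?") {
  first <- scan(file, what = character(), nlines = 1L, quiet = TRUE)
  hasHeader <- anyNA(suppressWarnings(as.numeric(first[first != "NA"])))
  g <- as.matrix(read.table(file, header = hasHeader))
  storage.mode(g) <- "double"
  new("GenotypeMatrix", dosages = g, snpPositions = as.numeric(positions),
      chromosome = chromosome)
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field into dosages of the alternate allele.  Multi-allelic
#' sites are rejected with a message naming the offending records.
#'
#' @param file path to a VCF (uncompressed or gzipped).
#' @return A [GenotypeMatrix-class] with positions and chromosome taken
#'   from the VCF.
#' @export
readVCFGenotypes <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("package 'vcfR' is required to read VCF files")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stopf("multi-allelic sites not supported: %s",
          paste(head(vcfR::getID(v)[multi], 5L), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1L, 2L), function(x) {
    if (is.na(x)) return(NA_real_)
    a <- strsplit(x, "[/|]")[[1L]]
    if (any(a == ".")) return(NA_real_)
    sum(as.numeric(a))
  })
  chrom <- unique(vcfR::getCHROM(v))
  if (length(chrom) != 1L)
    stopf("VCF must contain a single chromosome (found %d)", length(chrom))
  new("GenotypeMatrix", dosages = t(dos),
      snpPositions = as.numeric(vcfR::getPOS(v)), chromosome = chrom)
}

#' Read a Hi-C contact map from triplets
#'
#' Accepts a headerless 3-column \code{bin_i bin_j count} TSV (1-based) or
#' a MatrixMarket coordinate file.
#'
#' @param file path.
#' @param p number of bins; inferred from the data when \code{NULL}.
#' @param binSize bin width in bp.
#' @param chromosome chromosome label.
#' @return A [ContactMap-class].
#' @export
readContactMap <- function(file, p = NULL, binSize = 40000,
                           chromosome = "chr?") {
  first <- readLines(file, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    M <- as(Matrix::readMM(file), "TsparseMatrix")
    i <- M@i + 1L; j <- M@j + 1L; x <- M@x
    if (is.null(p)) p <- nrow(M)
  } else {
    tab <- read.table(file, header = FALSE)
    i <- tab[[1L]]; j <- tab[[2L]]; x <- tab[[3L]]
    if (is.null(p)) p <- max(i, j)
  }
  new("ContactMap", p = as.integer(p), binSize = binSize,
      binI = as.integer(i), binJ = as.integer(j), counts = as.numeric(x),
      chromosome = chromosome)
}
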