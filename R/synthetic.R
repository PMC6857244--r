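#' @include genomics.R
NULL

#' PlantedStructure: ground-truth parameters for synthetic inputs
#'
#' Describes \code{p} ordered loci partitioned into contiguous blocks by
#' the cut points \code{boundaries} (block \code{k} starts at
#' \code{boundaries[k-1]}; cut points are strictly increasing within
#' \code{[2, p]}), together with the generator parameters used to emulate
#' the three kinds of input the clustering consumes:
#' block-structured band similarities, genotypes with distance-decaying LD,
#' and Hi-C contact maps with distance decay plus TAD enrichment.
#'
#' Defaults define the simulation conditions used throughout the package's
#' tests: within-block similarity 1 against between-block 0.1 with Gaussian
#' noise of sd 0.1 (a strong, roughly 9-sigma contrast); LD copying
#' probability \eqn{\rho = 0.9} at minor-allele frequency 0.25; Hi-C decay
#' \eqn{\lambda_{ij} = \mathrm{base}\,(1+|i-j|)^{-\alpha}} with
#' \eqn{\alpha = 1}, base intensity 100 and a 5-fold within-TAD boost.
#'
#' @slot p number of loci/bins.
#' @slot boundaries integer cut points in \code{[2, p]}.
#' @slot within,between,noise block-similarity levels and noise sd
#'   (\code{within > between >= 0}).
#' @slot rho first-order haplotype copying probability, \code{0 <= rho < 1}.
#' @slot maf minor-allele frequency, in (0, 0.5].
#' @slot missingRate genotype missingness rate, in [0, 1).
#' @slot alpha Hi-C distance-decay exponent (> 0).
#' @slot base Hi-C Poisson base intensity.
#' @slot boost within-TAD intensity multiplier (>= 1).
#' @slot seed integer seed; all generators are bit-reproducible given the
#'   parameters and the seed (independent per-generator streams are derived
#'   from it).
#' @seealso [plantedStructure()], [simBlockSimilarity()],
#'   [simGenotypes()], [simContactMap()]
#' @export
setClass("PlantedStructure",
  representation(p = "integer", boundaries = "integer", within = "numeric",
                 between = "numeric", noise = "numeric", rho = "numeric",
                 maf = "numeric", missingRate = "numeric", alpha = "numeric",
                 base = "numeric", boost = "numeric", seed = "integer"))

setValidity("PlantedStructure", function(object) {
  p <- object@p
  b <- object@boundaries
  if (p < 2L) return("p must be >= 2")
  if (length(b) && (is.unsorted(b, strictly = TRUE) || min(b) < 2L || max(b) > p))
    return("boundaries must be strictly increasing within [2, p]")
  if (!(object@within >= object@between && object@between >= 0))
    return("need within >= between >= 0")
  if (object@noise < 0) return("noise sd must be >= 0")
  if (object@rho < 0 || object@rho >= 1) return("rho must be in [0, 1)")
  if (object@maf <= 0 || object@maf > 0.5) return("maf must be in (0, 0.5]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be in [0, 1)")
  if (object@alpha <= 0) return("alpha must be > 0")
  if (object@base <= 0 || object@boost < 1)
    return("need base > 0 and boost >= 1")
  TRUE
})

setMethod("nObjects", "PlantedStructure", function(x) x@p)

setMethod("show", "PlantedStructure", function(object) {
  cat(sprintf("PlantedStructure: p = %d, %d planted blocks, seed = %d\n",
              object@p, length(object@boundaries) + 1L, object@seed))
})

#' Construct a PlantedStructure
#'
#' @param p number of loci.
#' @param K number of equal-sized blocks (used when \code{boundaries} is
#'   \code{NULL}).
#' @param boundaries explicit cut points (overrides \code{K}).
#' @param within,between,noise,rho,maf,missingRate,alpha,base,boost see
#'   [PlantedStructure-class].
#' @param seed RNG seed.
#' @return A [PlantedStructure-class].
#' @examples
#' ps <- plantedStructure(p = 100, K = 4, seed = 7)
#' sim <- simBlockSimilarity(ps, h = 30)
#' table(sim$labels)
#' @export
plantedStructure <- function(p, K = 1L, boundaries = NULL, within = 1,
                             between = 0.1, noise = 0.1, rho = 0.9,
                             maf = 0.25, missingRate = 0, alpha = 1,
                             base = 100, boost = 5, seed = 1L) {
  if (is.null(boundaries)) {
    boundaries <- if (K > 1L) round(seq_len(K - 1L) * p / K) + 1L else integer(0)
  }
  new("PlantedStructure", p = as.integer(p),
      boundaries = as.integer(boundaries), within = within,
      between = between, noise = noise, rho = rho, maf = maf,
      missingRate = missingRate, alpha = alpha, base = base, boost = boost,
      seed = as.integer(seed))
}

#' Planted block labels
#' @param ps a [PlantedStructure-class].
#' @return Integer vector of length \code{p}: the planted block of each
#'   locus, numbered left to right.
#' @export
plantedLabels <- function(ps) {
  findInterval(seq_len(ps@p), c(1L, ps@boundaries))
}

#' Generate a band similarity with planted contiguous blocks
#'
#' \eqn{s_{ij}} equals \code{within} plus noise when \code{i} and \code{j}
#' share a planted block, \code{between} plus noise otherwise, truncated to
#' the first \code{h} diagonals; symmetric and bit-reproducible per seed.
#'
#' @param ps a [PlantedStructure-class].
#' @param h bandwidth (default: full).
#' @return \code{list(similarity = BandSimilarity, labels = integer truth)}.
#' @export
simBlockSimilarity <- function(ps, h = ps@p) {
  p <- ps@p
  h <- checkBandwidthArg(h, p)
  labels <- plantedLabels(ps)
  band <- withSeed(streamSeed(ps@seed, 1L), {
    b <- matrix(0, p, h)
    for (d in 0:(h - 1L)) {
      i <- seq_len(p - d)
      mu <- ifelse(labels[i] == labels[i + d], ps@within, ps@between)
      b[i, d + 1L] <- mu + ps@noise * rnorm(length(i))
    }
    b
  })
  list(similarity = newBandSimilarity(band), labels = labels)
}

#' Generate genotypes with block-structured, distance-decaying LD
#'
#' Haplotypes follow a first-order copying chain: within a planted block
#' the allele at SNP \code{t} is copied from SNP \code{t - 1} with
#' probability \code{rho} and redrawn at frequency \code{maf} otherwise;
#' the chain resets at every block boundary, so expected \eqn{r^2} decays
#' like \eqn{\rho^{2d}} with distance \code{d} inside blocks and vanishes
#' across boundaries.  Genotypes are sums of two independent haplotypes;
#' missingness is applied completely at random at rate \code{missingRate}.
#'
#' @param ps a [PlantedStructure-class].
#' @param n number of individuals.
#' @return \code{list(genotypes = GenotypeMatrix, labels = integer truth)}.
#' @export
simGenotypes <- function(ps, n) {
  p <- ps@p
  labels <- plantedLabels(ps)
  dos <- withSeed(streamSeed(ps@seed, 2L), {
    hap <- matrix(0L, 2L * n, p)
    hap[, 1L] <- rbinom(2L * n, 1L, ps@maf)
    for (t in seq_len(p)[-1L]) {
      fresh <- rbinom(2L * n, 1L, ps@maf)
      if (labels[t] == labels[t - 1L]) {
        copy <- runif(2L * n) < ps@rho
        hap[, t] <- ifelse(copy, hap[, t - 1L], fresh)
      } else {
        hap[, t] <- fresh
      }
    }
    g <- hap[seq_len(n), , drop = FALSE] +
      hap[n + seq_len(n), , drop = FALSE]
    storage.mode(g) <- "double"
    if (ps@missingRate > 0)
      g[runif(length(g)) < ps@missingRate] <- NA_real_
    g
  })
  G <- new("GenotypeMatrix", dosages = dos,
           snpPositions = as.numeric(seq_len(p) * 1000L),
           chromosome = "chrSim")
  list(genotypes = G, labels = labels)
}

#' Generate a Hi-C contact map with distance decay and planted TADs
#'
#' Expected counts follow a power-law distance decay,
#' \eqn{\lambda_{ij} = \mathrm{base}\,(1 + |i-j|)^{-\alpha}}, multiplied by
#' \code{boost} when both bins lie in the same planted TAD; observed
#' counts are Poisson.  Only in-band pairs with a positive count are
#' emitted as triplets (zeros are implicit), matching the sparse,
#' diagonal-concentrated structure of real intra-chromosomal maps.
#'
#' @param ps a [PlantedStructure-class].
#' @param h bandwidth of emitted pairs (default: full).
#' @param binSize bin width in bp.
#' @return \code{list(map = ContactMap, labels = integer truth)}.
#' @export
simContactMap <- function(ps, h = ps@p, binSize = 40000) {
  p <- ps@p
  h <- checkBandwidthArg(h, p)
  labels <- plantedLabels(ps)
  trip <- withSeed(streamSeed(ps@seed, 3L), {
    ii <- integer(0); jj <- integer(0); cc <- integer(0)
    for (d in 0:(h - 1L)) {
      i <- seq_len(p - d)
      lam <- ps@base * (1 + d)^(-ps@alpha) *
        ifelse(labels[i] == labels[i + d], ps@boost, 1)
      cnt <- rpois(length(i), lam)
      pos <- cnt > 0L
      ii <- c(ii, i[pos]); jj <- c(jj, i[pos] + d); cc <- c(cc, cnt[pos])
    }
    list(i = ii, j = jj, c = cc)
  })
  map <- new("ContactMap", p = p, binSize = binSize, binI = trip$i,
             binJ = trip$j, counts = as.numeric(trip$c),
             chromosome = "chrSim")
  list(map = map, labels = labels)
}
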