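makeGenotypes <- function(dos, pos = NULL) {
  new("GenotypeMatrix", dosages = dos,
      snpPositions = if (is.null(pos)) numeric(0) else as.numeric(pos),
      chromosome = "chrT")
}

test_that("LD r-squared behaves like squared correlation of dosages", {
  set.seed(501)
  g1 <- rbinom(40, 2, 0.4)
  ## duplicated SNP: r2 = 1; complemented SNP: r2 = 1 (sign-invariant)
  G <- makeGenotypes(cbind(g1, g1, 2 - g1))
  B <- ldBand(G, h = 3)
  M <- bandToDense(B)
  expect_equal(diag(M), c(1, 1, 1))
  expect_equal(M[1, 2], 1)
  expect_equal(M[1, 3], 1)

  ## independent SNPs at large n: r2 below 0.01
  set.seed(502)
  n <- 1e4
  G2 <- makeGenotypes(cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3)))
  expect_lt(bandToDense(ldBand(G2, h = 2))[1, 2], 0.01)

  ## r2 matches cor()^2 with pairwise-complete missing data
  set.seed(503)
  dos <- matrix(rbinom(300, 2, 0.35), 50, 6)
  dos[sample(300, 30)] <- NA
  G3 <- makeGenotypes(dos)
  B3 <- ldBand(G3, h = 6)
  M3 <- bandToDense(B3)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(M3[i, j],
                 suppressWarnings(cor(dos[, i], dos[, j],
                                      use = "pairwise.complete.obs"))^2,
                 tolerance = 1e-12)
  expect_true(all(M3 >= 0 & M3 <= 1))
})

test_that("monomorphic SNPs yield zero similarity with a message", {
  g <- cbind(rep(1, 10), rbinom(10, 2, 0.5), rep(0, 10))
  g[1, 2] <- 1  # ensure polymorphic middle SNP
  expect_message(B <- ldBand(makeGenotypes(g), h = 3), "monomorphic")
  M <- bandToDense(B)
  expect_equal(M[1, 2], 0)
  expect_equal(M[2, 3], 0)
  expect_error(ldBand(makeGenotypes(matrix(1, 5, 3)), h = 3),
               "monomorphic")
})

test_that("LD bands nest consistently across bandwidths", {
  ps <- plantedStructure(p = 30, K = 3, seed = 13)
  G <- simGenotypes(ps, n = 80)$genotypes
  B5 <- ldBand(G, h = 5)
  B12 <- ldBand(G, h = 12)
  expect_equal(bandValues(B12)[, 1:5], bandValues(B5))
})

test_that("Hi-C similarity is log1p of counts within the band", {
  cm <- new("ContactMap", p = 4L, binSize = 100, binI = c(1L, 1L, 2L),
            binJ = c(1L, 2L, 4L), counts = c(3, 1, 7), chromosome = "chrT")
  B <- hicBand(cm, h = 2)
  M <- bandToDense(B)
  expect_equal(M[1, 1], log(4))
  expect_equal(M[1, 2], log(2))   # count 1 -> log 2
  expect_equal(M[2, 4], 0)        # beyond band: dropped
  expect_equal(M[3, 4], 0)        # absent pair: log1p(0) = 0
  expect_error(new("ContactMap", p = 2L, binSize = 1, binI = 1L,
                   binJ = 2L, counts = -1, chromosome = "x"),
               "nonnegative")
})

test_that("clusters export as tiling BED/GRanges intervals", {
  ## one cluster over bins 1-10 at 40 kb: chrN 0 400000
  f <- tempfile(fileext = ".bed")
  writeClustersBed(rep(1L, 10), binSize = 40000, chromosome = "chrN",
                   file = f)
  bed <- read.table(f)
  expect_equal(bed[[1]], "chrN")
  expect_equal(bed[[2]], 0)
  expect_equal(bed[[3]], 400000)
  expect_equal(bed[[4]], "cluster_1")

  ## K = p singletons: adjacent, non-overlapping records
  writeClustersBed(1:6, binSize = 100, chromosome = "chrN", file = f)
  bed <- read.table(f)
  expect_equal(nrow(bed), 6)
  expect_equal(bed[[2]], seq(0, 500, by = 100))
  expect_equal(bed[[3]], seq(100, 600, by = 100))

  ## random cuts tile the binned chromosome with no gaps or overlaps
  set.seed(511)
  B <- bandFromDense(abs(randBandMatrix(40, 8)), h = 8)
  D <- suppressWarnings(bandClust(B))
  for (K in c(2, 7, 19)) {
    lab <- cutClusters(D, K)
    gr <- clustersToGRanges(lab, binSize = 1000, chromosome = "chr2")
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    expect_equal(st[1], 1)
    expect_equal(en[length(en)], 40 * 1000)
    expect_equal(st[-1], en[-length(en)] + 1)
  }

  ## SNP-position mode spans first to last SNP of each cluster
  gr <- clustersToGRanges(c(1, 1, 2), positions = c(100, 250, 900),
                          chromosome = "chr3")
  expect_equal(GenomicRanges::start(gr), c(100, 900))
  expect_equal(GenomicRanges::end(gr), c(250, 900))

  expect_error(clustersToGRanges(c(1, 2, 1), binSize = 10), "contiguous")
  expect_error(clustersToGRanges(1:3), "exactly one")
})

test_that("bandwidth selection finds the true bandwidth by stability", {
  set.seed(521)
  M <- randBandMatrix(60, 10)
  builder <- function(h) bandFromDense(M, h = h)
  h <- suppressWarnings(selectBandwidth(builder, c(5, 10, 20, 40),
                                        stability = 1))
  expect_equal(as.numeric(h), 10)
  expect_s3_class(attr(h, "trace"), "data.frame")

  expect_error(selectBandwidth(builder, c(5)), "at least 2")
  expect_error(selectBandwidth(builder, c(10, 5)), "increasing")

  ## schedule exhausted: error carries the comparison trace
  set.seed(522)
  Mfull <- randBandMatrix(60, 60)
  err <- tryCatch(
    suppressWarnings(selectBandwidth(function(h) bandFromDense(Mfull, h = h),
                                     c(2, 4, 6), stability = 1)),
    error = identity)
  expect_s3_class(err, "error")
  expect_s3_class(attr(err, "trace"), "data.frame")
})

test_that("LD-based bandwidth selection stabilises well below p", {
  ps <- plantedStructure(p = 80, K = 4, seed = 17)
  G <- simGenotypes(ps, n = 300)$genotypes
  h <- suppressWarnings(selectBandwidth(function(h) ldBand(G, h),
                                        c(10, 20, 40, 80), stability = 0.98))
  expect_lt(as.numeric(h), 80)
})

test_that("dosage and VCF readers produce valid genotype matrices", {
  set.seed(531)
  dos <- matrix(rbinom(60, 2, 0.4), 10, 6)
  f <- tempfile(fileext = ".tsv")
  write.table(dos, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  G <- readDosageMatrix(f)
  expect_equal(unname(G@dosages), dos, ignore_attr = TRUE)

  ## minimal single-chromosome VCF
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
           "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
           "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
           "chr1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1")
  fv <- tempfile(fileext = ".vcf")
  writeLines(vcf, fv)
  Gv <- readVCFGenotypes(fv)
  expect_equal(nObjects(Gv), 3L)
  expect_equal(objectPositions(Gv), c(100, 200, 300))
  expect_equal(unname(Gv@dosages["A", ]), c(0, 2, 1))
  expect_equal(unname(Gv@dosages["B", ]), c(1, NA, 2))

  ## multi-allelic sites are rejected
  vcf2 <- c(vcf[1:2], "chr1\t100\trsX\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2")
  fv2 <- tempfile(fileext = ".vcf")
  writeLines(vcf2, fv2)
  expect_error(readVCFGenotypes(fv2), "multi-allelic")
})

test_that("contact-map reader accepts triplet TSV and MatrixMarket", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("1\t1\t5", "1\t2\t3", "3\t3\t2"), f)
  cm <- readContactMap(f, binSize = 500)
  expect_equal(nObjects(cm), 3L)
  expect_equal(cm@counts, c(5, 3, 2))
  B <- hicBand(cm, h = 3)
  expect_equal(bandToDense(B)[1, 2], log(4))
})
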