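test_that("dense construction keeps exactly the first h diagonals", {
  B <- bandFromDense(diag(3), h = 1)
  expect_equal(nObjects(B), 3L)
  expect_equal(bandwidth(B), 1L)
  expect_equal(as.numeric(bandValues(B)), c(1, 1, 1))

  expect_error(bandFromDense(matrix(1, 3, 3), h = 2, strict = TRUE),
               "strict band violation")
  ## non-strict silently drops out-of-band mass
  B2 <- bandFromDense(matrix(1, 3, 3), h = 2)
  M2 <- bandToDense(B2)
  expect_equal(M2[1, 3], 0)
  expect_equal(M2[1, 2], 1)

  set.seed(11)
  M <- matrix(rnorm(100), 10); M <- (M + t(M)) / 2
  expect_identical(bandToDense(bandFromDense(M, h = 10)), M)

  expect_error(bandFromDense(matrix(1, 2, 3)), "square")
  asym <- matrix(c(0, 1, 0, 0), 2)
  expect_error(bandFromDense(asym), "not symmetric")
  expect_error(bandFromDense(diag(3), h = 0), "bandwidth")
  expect_error(bandFromDense(diag(3), h = 4), "bandwidth")
  expect_error(bandFromDense(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("triplet construction matches dense construction and flags gaps", {
  expect_warning(B <- bandFromTriplets(1L, 2L, 0.5, p = 3, h = 2),
                 "diagonal")
  M <- bandToDense(B)
  expect_equal(M[1, 2], 0.5)
  expect_equal(M[2, 1], 0.5)
  expect_equal(diag(M), c(0, 0, 0))

  expect_warning(B0 <- bandFromTriplets(integer(0), integer(0), numeric(0),
                                        p = 2, h = 2), "diagonal")
  expect_equal(bandToDense(B0), matrix(0, 2, 2))

  ## 50 random in-band triplets equal the dense route
  set.seed(21)
  p <- 12; h <- 4
  i <- sample(p, 50, replace = TRUE)
  d <- sample(0:(h - 1), 50, replace = TRUE)
  keep <- !duplicated(cbind(i, d)) & i + d <= p
  i <- i[keep]; j <- (i + d[keep]); x <- rnorm(sum(keep))
  M <- matrix(0, p, p)
  M[cbind(i, j)] <- x; M[cbind(j, i)] <- x
  Bt <- suppressWarnings(bandFromTriplets(i, j, x, p = p, h = h))
  expect_equal(bandToDense(Bt), bandToDense(bandFromDense(M, h = h)))

  expect_error(bandFromTriplets(1L, 5L, 1, p = 3, h = 3), "out of range")
  expect_error(suppressWarnings(
    bandFromTriplets(c(1L, 2L), c(2L, 1L), c(1, 2), p = 3, h = 3)),
    "conflicting")
  ## mirrored duplicates with agreeing values are accepted
  expect_silent(suppressWarnings(
    bandFromTriplets(c(1L, 2L, 1L, 2L, 3L), c(2L, 1L, 1L, 2L, 3L),
                     c(1, 1, 1, 1, 1), p = 3, h = 3)))
})

test_that("dissimilarity conversion reproduces Euclidean Ward exactly", {
  ## identical objects: constant similarity, all linkages zero
  B <- bandFromDissimilarity(matrix(0, 4, 4))
  D <- bandClust(B)
  expect_equal(mergeHeights(D), rep(0, 3))

  ## two points at distance 2: s11 = s22 = 2, s12 = 0, delta = 2
  D2 <- matrix(c(0, 2, 2, 0), 2)
  B2 <- bandFromDissimilarity(D2)
  expect_equal(bandToDense(B2), matrix(c(2, 0, 0, 2), 2))
  expect_equal(mergeHeights(bandClust(B2)), 2)

  ## 10 points on a line: same hierarchy and heights as Ward on the
  ## inner-product similarity (row/column offsets cancel in the linkage)
  set.seed(31)
  x <- sort(rnorm(10))
  Ddist <- as.matrix(dist(x))
  Bd <- bandFromDissimilarity(Ddist)
  Dd <- bandClust(Bd)
  Dip <- naiveClust(outer(x, x))
  expect_true(sameMergeSequence(Dd, Dip))
  expect_equal(mergeHeights(Dd), mergeHeights(Dip), tolerance = 1e-10)
  ## and every height equals the classical ESS increase
  X <- matrix(x, ncol = 1)
  mm <- merges(Dd)
  ess <- vapply(seq_len(nrow(mm)), function(s)
    essWard(X, mm[s, "i"], mm[s, "m"], mm[s, "j"]), numeric(1))
  expect_equal(mergeHeights(Dd), ess, tolerance = 1e-8)

  expect_error(bandFromDissimilarity(matrix(c(0, -1, -1, 0), 2)),
               "nonnegative")
  expect_error(bandFromDissimilarity(diag(2)), "diagonal")
})

test_that("diagonal shift leaves the hierarchy invariant (Miyamoto)", {
  B <- bandFromDense(diag(2), h = 2)
  expect_equal(bandToDense(shiftDiagonal(B, 0)), bandToDense(B))
  B3 <- shiftDiagonal(B, 3)
  expect_equal(diag(bandToDense(B3)), c(4, 4))
  expect_equal(mergeHeights(bandClust(B3)),
               mergeHeights(bandClust(B)) + 3)

  set.seed(41)
  for (rep in 1:20) {
    p <- sample(5:40, 1); h <- sample(2:p, 1)
    B <- bandFromDense(randBandMatrix(p, h), h = h)
    lam <- rnorm(1, sd = 5)
    D0 <- suppressWarnings(bandClust(B))
    D1 <- suppressWarnings(bandClust(shiftDiagonal(B, lam)))
    expect_true(sameMergeSequence(D0, D1))
    expect_equal(mergeHeights(D1), mergeHeights(D0) + lam,
                 tolerance = 1e-8)
  }
})

test_that("uniform shift of all entries leaves Ward linkages unchanged", {
  set.seed(51)
  p <- 15
  M <- matrix(rnorm(p * p), p); M <- (M + t(M)) / 2
  c0 <- 2.7
  D0 <- suppressWarnings(bandClust(bandFromDense(M, h = p)))
  D1 <- suppressWarnings(bandClust(bandFromDense(M + c0, h = p)))
  expect_true(sameMergeSequence(D0, D1))
  expect_equal(mergeHeights(D1), mergeHeights(D0), tolerance = 1e-10)
})

test_that("similarity file readers round-trip dense and sparse formats", {
  set.seed(61)
  M <- randBandMatrix(8, 3)
  f <- tempfile(fileext = ".tsv")
  write.table(M, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  B <- readDenseSimilarity(f, h = 3)
  expect_equal(bandToDense(B), bandToDense(bandFromDense(M, h = 3)))

  ## labelled variant with header row and label column
  dimnames(M) <- list(paste0("s", 1:8), paste0("s", 1:8))
  f2 <- tempfile(fileext = ".tsv")
  write.table(M, f2, sep = "\t", quote = FALSE)
  B2 <- readDenseSimilarity(f2, h = 3)
  expect_equal(objectLabels(B2), paste0("s", 1:8))

  ## MatrixMarket symmetric coordinate round trip
  sm <- Matrix::forceSymmetric(Matrix::Matrix(M, sparse = TRUE))
  f3 <- tempfile(fileext = ".mtx")
  Matrix::writeMM(sm, f3)
  B3 <- readTripletSimilarity(f3, h = 3)
  expect_equal(bandToDense(B3), bandToDense(B))

  ## 3-column TSV
  ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  f4 <- tempfile(fileext = ".tsv")
  write.table(data.frame(ut[, 1], ut[, 2], M[ut]), f4, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  B4 <- readTripletSimilarity(f4, p = 8, h = 3)
  expect_equal(bandToDense(B4), bandToDense(B))
})
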