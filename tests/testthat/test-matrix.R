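test_that("binning conserves pairs and matches a direct tally", {
  lens <- c(chrA = 95000, chrB = 52000)
  set.seed(13)
  n <- 10000
  pr <- data.frame(read_id = paste0("r", 1:n),
                   chrom1 = sample(names(lens), n, TRUE), pos1 = NA,
                   strand1 = "+",
                   chrom2 = sample(names(lens), n, TRUE), pos2 = NA,
                   strand2 = "-")
  pr$pos1 <- floor(runif(n) * lens[pr$chrom1])
  pr$pos2 <- floor(runif(n) * lens[pr$chrom2])
  m <- binPairs(pr, lens, 1e4)
  expect_equal(sum(m@counts[upper.tri(m@counts, diag = TRUE)]), n)
  # marginals equal a direct per-bin tally of pair ends
  idx <- c(binIndex(m, pr$chrom1, pr$pos1), binIndex(m, pr$chrom2, pr$pos2))
  tal <- tabulate(idx, nbins = nrow(m@counts))
  marg <- rowSums(m@counts) + diag(m@counts)  # diagonal holds both ends
  expect_equal(unname(marg), tal)
  # symmetry
  expect_equal(m@counts, t(m@counts))
})

test_that("half-open binning places a 5kb/25kb pair in bins 1 and 3", {
  lens <- c(chr1 = 6e4)
  pr <- data.frame(read_id = "r", chrom1 = "chr1", pos1 = 5000, strand1 = "+",
                   chrom2 = "chr1", pos2 = 25000, strand2 = "-")
  m <- binPairs(pr, lens, 1e4)
  expect_equal(m@counts[1, 3], 1)
  expect_equal(m@counts[3, 1], 1)
  expect_error(binPairs(transform(pr, pos2 = 7e4), lens, 1e4), "beyond")
})

test_that("bimodal column sums are split at the first-mode valley", {
  set.seed(42)
  n <- 330
  # column sums ~N(10,2) for the first 30 bins, ~N(200,20) for the rest,
  # constructed via a rank-1 bias structure
  target <- c(pmax(rnorm(30, 10, 2), 3), rnorm(300, 200, 20))
  b <- sqrt(target)
  W <- outer(b, b) * matrix(rgamma(n * n, 20, 20), n, n)
  W <- (W + t(W)) / 2
  W <- W * sum(target) / sum(2 * W)       # calibrate total
  m <- asHiC(W)
  m <- maskColumns(m)
  cs <- colSums(W)
  # histogram-valley oracle: any threshold between the modes separates them
  expect_true(max(cs[1:30]) < min(cs[31:n]))
  expect_equal(maskedBins(m), 1:30)
})

test_that("unimodal tight sums mask only zero columns", {
  set.seed(7)
  W <- matrix(rpois(100 * 100, 30), 100, 100)
  W <- W + t(W)
  W[, 17] <- 0; W[17, ] <- 0
  m <- maskColumns(asHiC(W))
  expect_equal(maskedBins(m), 17L)
  Wz <- matrix(0, 5, 5)
  expect_error(maskColumns(asHiC(Wz)), "all columns")
})

test_that("ICE at tight tolerance matches a Sinkhorn fixed-point oracle", {
  set.seed(31)
  for (trial in 1:5) {
    A <- matrix(runif(400, 0.5, 2), 20, 20)
    A <- A + t(A)
    m <- asHiC(A)
    ice <- iceNormalize(m, maxDev = 1e-8, maxIter = 10000)
    # independent symmetric Sinkhorn run to machine precision
    W <- A
    repeat {
      s <- rowSums(W)
      if (max(abs(s - mean(s))) / mean(s) < 1e-13) break
      W <- W / sqrt(outer(s, s)) * mean(s)
    }
    W <- W * sum(A) / sum(W)
    expect_lt(max(abs(contactCounts(ice) - W)), 1e-6)
  }
})

test_that("the truncated 10% stop bounds the row-sum deviation", {
  set.seed(33)
  for (trial in 1:5) {
    A <- matrix(rpois(625, 8) * runif(625, 0.2, 3), 25, 25)
    A <- A + t(A) + 1
    ice <- iceNormalize(asHiC(A), maxDev = 0.10)
    expect_lte(rowSumDeviation(ice), 0.10)
  }
})

test_that("a constant matrix is already balanced (converges immediately)", {
  m <- asHiC(matrix(2, 6, 6))
  ice <- iceNormalize(m, 0.10)
  expect_equal(attr(contactCounts(ice), "iceIterations"), 0L)
  expect_equal(unname(binBiases(ice)), rep(1, 6))
})

test_that("normalization absorbs a global scalar into the biases", {
  set.seed(35)
  A <- matrix(runif(225, 1, 4), 15, 15); A <- A + t(A)
  n1 <- iceNormalize(asHiC(A), 1e-10, 10000)
  n2 <- iceNormalize(asHiC(A * 7), 1e-10, 10000)
  r <- contactCounts(n2) / contactCounts(n1)
  expect_equal(max(r) / min(r), 1, tolerance = 1e-6)
})

test_that("merging sums raw counts and rejects mismatches", {
  lens <- c(chrA = 5e4)
  set.seed(37)
  pr <- data.frame(read_id = "r", chrom1 = "chrA", pos1 = c(100, 200, 300),
                   strand1 = "+", chrom2 = "chrA", pos2 = c(5000, 15000, 2000),
                   strand2 = "-")
  m1 <- binPairs(pr, lens, 1e4)
  m0 <- emptyHiCMatrix(lens, 1e4)
  expect_equal(contactCounts(mergeMatrices(m1, m0)), contactCounts(m1))
  m2 <- binPairs(pr, lens, 1e4)
  tot <- sum(contactCounts(mergeMatrices(m1, m2)))
  expect_equal(tot, sum(contactCounts(m1)) + sum(contactCounts(m2)))
  other <- emptyHiCMatrix(c(chrB = 5e4), 1e4)
  expect_error(mergeMatrices(m1, other), "incompatible")
})

test_that("dense and triplet text formats round-trip identically", {
  set.seed(39)
  A <- matrix(rpois(144, 4), 12, 12); A <- A + t(A)
  m <- maskColumns(asHiC(A))
  m <- iceNormalize(m, 0.1)
  attr(m@counts, "iceDeviation") <- NULL
  attr(m@counts, "iceIterations") <- NULL
  fd <- tempfile(); ft <- tempfile()
  writeHiCMatrix(m, fd, "dense")
  writeHiCMatrix(m, ft, "triplet")
  d <- readHiCMatrix(fd); t3 <- readHiCMatrix(ft)
  expect_equal(contactCounts(d), contactCounts(t3), tolerance = 1e-9)
  expect_equal(contactCounts(d), contactCounts(m), tolerance = 1e-9)
  expect_equal(maskedBins(d), maskedBins(m))
  expect_equal(d@normalized, TRUE)
})

test_that("chromosome submatrix extraction keeps mask and bias slices", {
  lens <- c(chrA = 3e4, chrB = 2e4)
  m <- emptyHiCMatrix(lens, 1e4)
  m@counts <- matrix(1, 5, 5); diag(m@counts) <- 2
  m@mask <- c(2L, 4L)
  sub <- chromosomeSubmatrix(m, "chrB")
  expect_equal(dim(contactCounts(sub)), c(2L, 2L))
  expect_equal(maskedBins(sub), 1L)   # genome bin 4 is chrB bin 1
})
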