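test_that("segment score matches a direct likelihood-ratio evaluation", {
  set.seed(17)
  A <- matrix(rpois(100, 12), 10, 10); A <- A + t(A)
  E <- decayExpectation(A)
  for (i in c(1, 3, 5)) for (j in c(6, 8, 10)) {
    # independent re-evaluation of the one-parameter Poisson LRT
    cells <- which(upper.tri(A, diag = TRUE) &
                   row(A) >= i & col(A) <= j & row(A) <= col(A))
    o <- A[cells]; e <- E[cells]
    w <- sum(o) / sum(e)
    want <- sum(o * log(w * e) - w * e) - sum(o * log(e) - e)
    expect_equal(segmentScore(A, E, i, j), want, tolerance = 1e-10)
  }
  expect_error(segmentScore(A, E, 5, 2), "invalid segment")
})

test_that("intensity ratio scales linearly with segment counts", {
  A <- matrix(10, 8, 8)
  E <- decayExpectation(A)
  B <- A
  B[2:4, 2:4] <- 20
  d <- intraTadDensity(B, 2, 4)
  # ML intensity of the doubled block doubles (minus the pooled-E dilution)
  expect_gt(d$ratio, 1.5)
  expect_equal(intraTadDensity(A, 2, 4)$ratio, 1)
  expect_equal(intraTadDensity(A, 2, 4)$flag, "higher")  # tie rule: >= 1
})

test_that("the DP equals exhaustive enumeration for small matrices", {
  set.seed(19)
  for (trial in 1:20) {
    n <- sample(6:12, 1)
    A <- matrix(rpois(n * n, sample(c(4, 10, 25), 1)), n, n)
    A <- A + t(A)
    seg <- optimalSegmentation(A, rescale = FALSE, refinePasses = 0L,
                               resolution = 1e4)
    brute <- bruteSegment(A)
    expect_equal(tadBorders(seg), brute$borders,
                 label = sprintf("trial %d", trial))
    expect_equal(seg@logLik, brute$score, tolerance = 1e-8)
  }
})

test_that("pure decay without block structure yields a single TAD", {
  sim <- simulateMatrix(40, integer(), 1, depth = 200, seed = 2)
  seg <- optimalSegmentation(sim$counts, resolution = 1e4)
  expect_equal(tadBorders(seg), 1L)
})

test_that("two planted blocks give one exact central border", {
  sim <- simulateMatrix(24, 13L, 4, depth = 200, seed = 3)
  seg <- optimalSegmentation(sim$counts, resolution = 1e4)
  expect_equal(tadBorders(seg), c(1L, 13L))
  # strongly separated blocks persist through every refinement
  expect_equal(borderStrengths(seg), c(10L, 10L))
  expect_true(all(borderStrengths(seg) >= 1 & borderStrengths(seg) <= 10))
})

test_that("planted borders are recovered within one bin on noisy chromosomes", {
  borders <- c(21L, 41L, 61L, 81L)
  hits <- 0L
  nseeds <- 25L
  for (s in seq_len(nseeds)) {
    sim <- simulateMatrix(100, borders, 3, depth = 100, seed = s)
    found <- tadBorders(optimalSegmentation(sim$counts, resolution = 1e4))[-1]
    hits <- hits + sum(vapply(borders, function(b)
      any(abs(found - b) <= 1), TRUE))
  }
  expect_gte(hits / (nseeds * length(borders)), 0.9)
})

test_that("penalized likelihood is non-decreasing in maxTadBins", {
  sim <- simulateMatrix(30, c(11L, 21L), 3, depth = 150, seed = 5)
  lls <- vapply(c(8L, 12L, 20L, 30L), function(mx)
    optimalSegmentation(sim$counts, maxTadBins = mx, refinePasses = 0L,
                        resolution = 1e4)@logLik, 0)
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("segmentation is invariant to a positive global rescale", {
  sim <- simulateMatrix(60, 31L, 3, depth = 100, seed = 7)
  s1 <- optimalSegmentation(sim$counts, resolution = 1e4)
  s2 <- optimalSegmentation(sim$counts * 37.5, resolution = 1e4)
  expect_equal(tadBorders(s1), tadBorders(s2))
  expect_equal(borderStrengths(s1), borderStrengths(s2))
})

test_that("borders avoid long masked runs and tiny inputs degrade gracefully", {
  sim <- simulateMatrix(40, 21L, 4, depth = 150, seed = 9)
  A <- sim$counts
  A[, 18:24] <- 0; A[18:24, ] <- 0          # masked run of 7 over the border
  seg <- optimalSegmentation(A, resolution = 1e4)
  expect_false(any(tadBorders(seg)[-1] %in% 18:24))
  tiny <- optimalSegmentation(matrix(5, 3, 3), minTadBins = 2L,
                              resolution = 1e4)
  expect_equal(tadBorders(tiny), 1L)
})

test_that("forceM returns the requested number of TADs", {
  sim <- simulateMatrix(40, c(15L, 27L), 3, depth = 150, seed = 11)
  seg <- optimalSegmentation(sim$counts, forceM = 5L, resolution = 1e4)
  expect_equal(length(tadBorders(seg)), 5L)
})

test_that("planted density flags recover enriched and depleted blocks", {
  set.seed(13)
  base <- matrix(rpois(40 * 40, 20), 40, 40); base <- base + t(base)
  hi <- base; hi[5:12, 5:12] <- hi[5:12, 5:12] * 4
  d <- intraTadDensity(hi, 5, 12)
  expect_gt(d$ratio, 2)
  expect_equal(d$flag, "higher")
  lo <- base
  lo[25:32, 25:32] <- round(lo[25:32, 25:32] * 0.3)
  d2 <- intraTadDensity(lo, 25, 32)
  expect_lt(d2$ratio, 1)
  expect_equal(d2$flag, "lower")
})

test_that("border TSV output round-trips positions in bp", {
  sim <- simulateMatrix(40, c(15L, 27L), 4, depth = 200, seed = 15)
  seg <- optimalSegmentation(sim$counts, resolution = 1e4, chrom = "chr2L")
  f <- tempfile(fileext = ".tsv")
  writeBorders(seg, f)
  pos <- readBorderBed(f)
  expect_equal(pos, (tadBorders(seg) - 1) * 1e4)
})
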