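test_that("z-scores match a two-pass oracle and are depth-invariant", {
  set.seed(41)
  A <- matrix(rpois(400, 30) + 1, 20, 20); A <- A + t(A)
  z <- zscoreMatrix(A)
  off <- row(A) != col(A)
  lx <- log10(A[off & A > 0])
  expect_equal(z[2, 5], (log10(A[2, 5]) - mean(lx)) / sd(lx),
               tolerance = 1e-12)
  expect_true(all(is.na(diag(z))))
  # doubling all counts shifts every log equally
  expect_equal(zscoreMatrix(A * 2), z, tolerance = 1e-10)
})

test_that("degenerate z inputs are guarded", {
  expect_error(zscoreMatrix(matrix(0, 10, 10)), "insufficient")
  expect_warning(zc <- zscoreMatrix(matrix(5, 10, 10) - diag(5, 10)),
                 "zero variance")
  expect_true(all(zc[row(zc) != col(zc)] == 0, na.rm = TRUE))
})

test_that("restraints encode occupancy, z cutoffs and the linear distance map", {
  set.seed(43)
  A <- matrix(rpois(900, 25) + 1, 30, 30); A <- A + t(A)
  z <- zscoreMatrix(A)
  p <- modelingParams(resolution = 1e4, scale = 0.01, lowfreq = -0.5,
                      upfreq = 0.5, maxdist = 1000)
  expect_equal(p$radius, 50)                       # 10 kb * 0.01 nm/bp / 2
  rs <- buildRestraints(z, p)
  consec <- rs@i + 1L == rs@j
  expect_true(all(rs@kind[consec] == "harmonic"))
  expect_equal(unique(rs@dist[consec]), 100)       # sum of radii
  # endpoint of the z -> distance map: strongest contact sits at 2 * radius
  zz <- z[cbind(rs@i, rs@j)]
  strongest <- which(!consec & !is.na(zz) & zz == max(zz[!consec], na.rm = TRUE))
  expect_equal(unique(rs@dist[strongest]), 100, tolerance = 1e-9)
  # boundary tie rule: z exactly at upfreq is attractive
  at <- !consec & !is.na(zz) & zz >= 0.5
  expect_true(all(rs@kind[at] == "harmonic"))
  lo <- !consec & !is.na(zz) & zz <= -0.5
  expect_true(all(rs@kind[lo] == "lower"))
  expect_true(all(rs@dist[lo] == 1000))            # proximal = maxdist
  # no-data pairs fall back to soft excluded volume
  ev <- !consec & is.na(zz)
  expect_true(all(rs@kind[ev] == "lower" & rs@dist[ev] == 100))
  expect_error(modelingParams(lowfreq = 1, upfreq = 0), "lowfreq")
})

test_that("the optimizer reaches exact minima of simple restraint sets", {
  rs <- new("RestraintSet", i = 1L, j = 2L, kind = "harmonic", dist = 100,
            k = 0.05, radius = 50, nParticles = 2L)
  m <- optimizeModel(rs, seed = 1)
  expect_equal(sqrt(sum((m$coords[1, ] - m$coords[2, ])^2)), 100,
               tolerance = 0.1)
  rs3 <- new("RestraintSet", i = c(1L, 2L), j = c(2L, 3L),
             kind = rep("harmonic", 2), dist = c(100, 100), k = c(0.05, 0.05),
             radius = 50, nParticles = 3L)
  m3 <- optimizeModel(rs3, seed = 2)
  for (b in 1:2)
    expect_equal(sqrt(sum((m3$coords[b, ] - m3$coords[b + 1, ])^2)), 100,
                 tolerance = 0.1)
})

test_that("the objective is invariant under rigid transforms", {
  set.seed(45)
  A <- matrix(rpois(625, 20) + 1, 25, 25); A <- A + t(A)
  rs <- buildRestraints(zscoreMatrix(A), modelingParams(maxdist = 800))
  X <- matrix(rnorm(75, sd = 300), 25, 3)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  Y <- X %*% Rx %*% Rz + matrix(rep(c(13, -7, 99), each = 25), 25, 3)
  expect_equal(restraintObjective(X, rs), restraintObjective(Y, rs),
               tolerance = 1e-8)
})

test_that("ensembles are deterministic, sorted, and respect nKeep", {
  rs3 <- new("RestraintSet", i = c(1L, 2L), j = c(2L, 3L),
             kind = rep("harmonic", 2), dist = c(100, 100), k = c(0.05, 0.05),
             radius = 50, nParticles = 3L)
  e1 <- generateEnsemble(rs3, 6, 4, baseSeed = 7, nSweeps = 50)
  e2 <- generateEnsemble(rs3, 6, 4, baseSeed = 7, nSweeps = 50)
  expect_identical(modelCoords(e1), modelCoords(e2))
  expect_equal(length(modelCoords(e1)), 4L)
  expect_false(is.unsorted(modelObjectives(e1)))
  single <- generateEnsemble(rs3, 1, 1, baseSeed = 3, nSweeps = 50)
  expect_equal(length(modelCoords(single)), 1L)
  expect_error(generateEnsemble(rs3, 2, 5), "nKeep")
})

test_that("model contact maps follow closed-form chain geometry", {
  chain <- toyStructure("straight", 10, step = 100)
  cm <- modelContactMap(list(chain), 150)
  d <- abs(row(cm) - col(cm))
  expect_true(all(cm[d == 1] == 1))
  expect_true(all(cm[d > 1] == 0))
  expect_equal(diag(cm), rep(1, 10))
  # limits of the cutoff
  expect_true(all(modelContactMap(list(chain), 1e9) == 1))
  cm0 <- modelContactMap(list(chain), 1e-6)
  expect_equal(cm0, diag(10))
  # monotone in dcutoff
  cmA <- modelContactMap(list(chain), 120)
  cmB <- modelContactMap(list(chain), 250)
  expect_true(all(cmB >= cmA))
})

test_that("excluded volume keeps unrestrained pairs apart", {
  set.seed(47)
  A <- matrix(rpois(400, 1.5), 20, 20); A <- A + t(A)  # sparse: zeros stay
  zz <- zscoreMatrix(A)
  free <- is.na(zz) & abs(row(zz) - col(zz)) > 1   # excluded-volume-only pairs
  expect_gt(sum(free), 0)
  p <- modelingParams(maxdist = 800)
  rs <- buildRestraints(zz, p)
  ens <- generateEnsemble(rs, 5, 5, baseSeed = 11, nSweeps = 150)
  for (m in modelCoords(ens)) {
    d <- as.matrix(dist(m))
    expect_lt(mean(d[free] < p$radius), 0.01)
  }
})

test_that("grid search returns the single point of a one-point grid", {
  set.seed(49)
  A <- matrix(rpois(225, 30) + 1, 15, 15); A <- A + t(A)
  gs <- optimizeParams(A, lowfreq = -0.6, upfreq = 0.3, maxdist = 600,
                       nSmall = 10L, baseSeed = 3, nSweeps = 50)
  expect_equal(nrow(gs$table), 1L)
  expect_equal(gs$best$lowfreq, -0.6)
  expect_equal(gs$best$maxdist, 600)
  expect_true(is.finite(gs$bestCorrelation))
  expect_error(optimizeParams(A, nSmall = 5L), "at least 10")
})

test_that("XYZ export writes one file per model plus a manifest", {
  rs3 <- new("RestraintSet", i = c(1L, 2L), j = c(2L, 3L),
             kind = rep("harmonic", 2), dist = c(100, 100), k = c(0.05, 0.05),
             radius = 50, nParticles = 3L)
  ens <- generateEnsemble(rs3, 2, 2, baseSeed = 5, nSweeps = 50,
                          region = list(chrom = "chr2L", start = 0,
                                        end = 3e4, resolution = 1e4))
  d <- tempfile()
  writeEnsembleXyz(ens, d)
  expect_equal(length(list.files(d, pattern = "\\.xyz$")), 2L)
  mf <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(mf$nModels, 2L)
  xyz <- read.table(list.files(d, pattern = "\\.xyz$", full.names = TRUE)[1],
                    sep = "\t")
  expect_equal(nrow(xyz), 3L)
})
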