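rigidTransform <- function(X, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  X %*% Rx %*% Ry %*% Rz + matrix(rep(rnorm(3, sd = 500), each = nrow(X)),
                                  nrow(X), 3)
}

test_that("superposition exactly inverts rigid transforms", {
  set.seed(51)
  for (trial in 1:25) {
    X <- matrix(rnorm(60, sd = 200), 20, 3)
    expect_lt(superpose(X, rigidTransform(X, trial))$rmsd, 1e-6)
  }
})

test_that("reflections are forbidden: mirror RMSD stays positive", {
  # chiral 4-point set
  X <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(30, 30, 100))
  mir <- X %*% diag(c(-1, 1, 1))
  s <- superpose(X, mir)
  expect_equal(det(s$rotation), 1, tolerance = 1e-10)
  expect_gt(s$rmsd, 1)
  # brute-force proper-rotation oracle on a small angle grid
  best <- Inf
  Xc <- sweep(X, 2, colMeans(X)); Mc <- sweep(mir, 2, colMeans(mir))
  for (a in seq(0, 2 * pi, length.out = 25))
    for (b in seq(0, pi, length.out = 13))
      for (c in seq(0, 2 * pi, length.out = 25)) {
        Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
        Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
        Rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
        R <- Rz1 %*% Ry %*% Rz2
        best <- min(best, sqrt(mean(rowSums((Xc - Mc %*% t(R))^2))))
      }
  expect_lte(s$rmsd, best + 1e-6)   # Kabsch at least as good as the grid
})

test_that("similarity is symmetric, maximal on the diagonal, and noise-ranked", {
  set.seed(53)
  rw <- toyStructure("random_walk", 25, 100, seed = 3)
  other <- toyStructure("random_walk", 25, 100, seed = 4)
  pert <- rw + matrix(rnorm(75, sd = 5), 25, 3)   # radius/10 jitter
  S <- similarityMatrix(list(rw, pert, other), dcutoff = 150)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 3))
  expect_gt(S[1, 2], S[1, 3])   # perturbation closer than an independent walk
})

test_that("MCL on a disconnected similarity graph returns its components", {
  S <- matrix(0, 20, 20)
  S[1:10, 1:10] <- 0.8; S[11:20, 11:20] <- 0.8
  diag(S) <- 1
  cl <- mclCluster(S)
  expect_equal(cl$nClusters, 2L)
  expect_equal(length(unique(cl$labels[1:10])), 1L)
  expect_equal(length(unique(cl$labels[11:20])), 1L)
  expect_false(cl$labels[1] == cl$labels[11])
  expect_equal(mclCluster(matrix(1, 1, 1))$nClusters, 1L)
  # cluster 1 is the most populated
  S2 <- matrix(0, 15, 15); S2[1:5, 1:5] <- 0.8; S2[6:15, 6:15] <- 0.8
  diag(S2) <- 1
  cl2 <- mclCluster(S2)
  expect_equal(sum(cl2$labels == 1L), 10L)
})

test_that("mirror-image ensembles split into separate clusters", {
  set.seed(55)
  rw <- toyStructure("random_walk", 30, 100, seed = 9)
  ens <- c(lapply(1:5, function(i) rw + matrix(rnorm(90, 0, 2), 30, 3)),
           lapply(1:5, function(i) rw %*% diag(c(-1, 1, 1)) +
                                   matrix(rnorm(90, 0, 2), 30, 3)))
  cl <- mclCluster(similarityMatrix(ens, dcutoff = 150))
  expect_gte(cl$nClusters, 2L)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  expect_false(cl$labels[1] == cl$labels[6])
})

test_that("accessibility spans its closed-form extremes", {
  expect_equal(accessibility(matrix(0, 1, 3), radius = 50), 100)
  # particle caged inside a dense spherical shell of blockers
  mesh <- tadmod:::.sphereMesh(200) * 120
  caged <- rbind(c(0, 0, 0), mesh)
  expect_lt(accessibility(caged, radius = 50, probeRadius = 75)[1], 5)
  # two touching spheres lose the facing cap: cap fraction (1 - cos a)/2
  two <- rbind(c(0, 0, 0), c(100, 0, 0))
  acc <- accessibility(two, radius = 50, probeRadius = 75, nMesh = 2000)
  r <- 50 + 75
  capFrac <- (1 - (100 / (2 * r))) / 2    # blocked fraction, cos a = d/(2r)
  expect_equal(acc[1], 100 * (1 - capFrac), tolerance = 2)
})

test_that("density and angles follow straight-chain geometry", {
  chain <- toyStructure("straight", 10, step = 100)
  expect_equal(chainDensity(chain, 1e4), rep(100, 10))
  a <- particleAngles(chain)
  expect_true(all(is.na(a[c(1, 10)])))
  expect_equal(a[2:9], rep(180, 8))
  # halving all coordinates doubles density
  expect_equal(chainDensity(chain / 2, 1e4), rep(200, 10))
  elbow <- rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0))
  expect_equal(particleAngles(elbow)[2], 90)
  tri <- rbind(c(0, 0, 0), c(100, 0, 0), c(50, 50 * sqrt(3), 0))
  expect_equal(particleAngles(tri)[2], 60)
  expect_warning(particleAngles(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))),
                 "coincident")
})

test_that("interaction counts match a brute-force distance check", {
  two <- rbind(c(0, 0, 0), c(200, 0, 0))
  expect_equal(interactionCount(two, 250), c(1, 1))
  expect_equal(interactionCount(two, 150), c(0, 0))
  set.seed(57)
  X <- matrix(rnorm(90, sd = 150), 30, 3)
  got <- interactionCount(X, 250)
  want <- vapply(1:30, function(i)
    sum(sqrt(colSums((t(X[-i, ]) - X[i, ])^2)) < 250), 0)
  expect_equal(got, want)
  # ensemble averaging
  expect_equal(interactionCount(list(two, two * 2), 250), c(0.5, 0.5))
})

test_that("structural measures are rigid-invariant and scale correctly", {
  set.seed(59)
  X <- toyStructure("random_walk", 20, 100, seed = 6)
  Y <- rigidTransform(X, 8)
  expect_equal(chainDensity(Y, 1e4), chainDensity(X, 1e4), tolerance = 1e-9)
  expect_equal(particleAngles(Y), particleAngles(X), tolerance = 1e-9)
  expect_equal(interactionCount(Y, 250), interactionCount(X, 250))
  # the probe mesh is fixed in the global frame, so accessibility is only
  # rigid-invariant up to mesh resolution
  accX <- accessibility(X, 50, nMesh = 1000)
  accY <- accessibility(Y, 50, nMesh = 1000)
  expect_lt(max(abs(accX - accY)), 3)
  # dilation: density shrinks, interactions never increase
  expect_equal(chainDensity(X * 2, 1e4), chainDensity(X, 1e4) / 2)
  expect_true(all(interactionCount(X * 2, 250) <= interactionCount(X, 250)))
})

test_that("collapsed chains are less accessible than extended ones", {
  straight <- toyStructure("straight", 50, 100)
  collapsed <- toyStructure("random_walk", 50, 100, seed = 12) * 0.4
  expect_gt(mean(accessibility(straight, 50)),
            mean(accessibility(collapsed, 50)))
})

test_that("chromatin colors follow the 50% coverage rule", {
  bed <- data.frame(chrom = "chr1",
                    start = c(0, 10000, 14000, 20000),
                    end = c(10000, 14000, 18000, 25000),
                    color = c("BLACK", "BLUE", "YELLOW", "RED"))
  cols <- assignColors(c(0, 10000, 20000), c(10000, 20000, 30000), bed, "chr1")
  # bin 1 fully black; bin 2 is 40% blue / 40% yellow -> white;
  # bin 3 exactly 50% red -> red (>= rule)
  expect_equal(cols, c("black", "white", "red"))
  expect_warning(
    assignColors(0, 1000,
                 data.frame(chrom = "c", start = c(0, 500), end = c(800, 900),
                            color = c("RED", "RED")), "c"),
    "overlapping")
})

test_that("per-color profiles report medians and Tukey significance", {
  set.seed(61)
  prof <- data.frame(accessibility = c(rnorm(40, 30, 1), rnorm(40, 50, 1)),
                     density = c(rnorm(40, 210, 5), rnorm(40, 180, 5)),
                     interactions = rnorm(80, 45, 2),
                     angle = rnorm(80, 90, 4))
  colors <- rep(c("black", "red"), each = 40)
  res <- profileByColor(prof, colors)
  expect_equal(unname(res$medians["black", "accessibility"]),
               median(prof$accessibility[1:40]))
  # ten-sigma offsets are significant; matched columns are not
  expect_lt(res$tukey$accessibility[1, "p adj"], 0.001)
  expect_lt(res$tukey$density[1, "p adj"], 0.001)
  expect_gt(res$tukey$interactions[1, "p adj"], 0.05)
  # colors with < 3 particles are excluded with a note
  res2 <- profileByColor(rbind(prof, prof[1, ]),
                         c(colors, "green"))
  expect_equal(res2$excluded, "green")
})
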