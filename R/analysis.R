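## Structural analysis of model ensembles: proper-rotation superposition,
## structural similarity + Markov clustering, and the four per-particle
## measures (accessibility, density, interactions, angle) with chromatin
## color annotation.

#' Rigid-body superposition (Kabsch)
#'
#' Optimal proper rotation (determinant +1, reflections forbidden) and
#' translation of B onto A minimizing RMSD, via SVD of the covariance
#' matrix; works for degenerate (collinear) configurations too.
#'
#' @param A,B n x 3 coordinate matrices.
#' @return list \code{rotation} (3 x 3), \code{translation} (length 3,
#'   applied after rotation), \code{rmsd} (nm), \code{Bfit} (B superposed
#'   onto A).
#' @export
superpose <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Bfit <- B0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A0 - Bfit)^2)))
  list(rotation = R, translation = ca, rmsd = rmsd,
       Bfit = sweep(Bfit, 2L, ca, `+`))
}

#' All-against-all structural similarity of an ensemble
#'
#' For each model pair, the score blends equally (i) the fraction of
#' particle pairs whose contact state at \code{dcutoff} agrees between the
#' two models and (ii) \code{1 - RMSD / maxRMSD} after proper-rotation
#' superposition, with \code{maxRMSD} the largest pairwise RMSD in the
#' ensemble.  Symmetric with unit diagonal.
#'
#' @param ensemble a \code{\linkS4class{ModelEnsemble}} or list of
#'   coordinate matrices.
#' @param dcutoff contact distance (nm).
#' @param weight weight of the contact-agreement term (default 0.5).
#' @return symmetric similarity matrix in [0, 1].
#' @export
similarityMatrix <- function(ensemble, dcutoff, weight = 0.5) {
  coords <- if (is(ensemble, "ModelEnsemble")) ensemble@coords else ensemble
  nm <- length(coords)
  contacts <- lapply(coords, function(x) {
    d <- as.matrix(dist(x))
    d[upper.tri(d)] < dcutoff
  })
  rmsd <- matrix(0, nm, nm)
  agree <- matrix(1, nm, nm)
  for (a in seq_len(nm)) for (b in seq_len(nm)) {
    if (b <= a) next
    rmsd[a, b] <- rmsd[b, a] <- superpose(coords[[a]], coords[[b]])$rmsd
    ag <- mean(contacts[[a]] == contacts[[b]])
    agree[a, b] <- agree[b, a] <- ag
  }
  maxR <- max(rmsd)
  if (maxR == 0) maxR <- 1
  sim <- weight * agree + (1 - weight) * (1 - rmsd / maxR)
  diag(sim) <- 1
  sim
}

#' Markov clustering (MCL) of a similarity matrix
#'
#' Alternating expansion (matrix squaring of the column-stochastic matrix)
#' and inflation (entry-wise power followed by column renormalisation) until
#' the matrix is idempotent; clusters are the attractor components.
#' Self-loops (the diagonal) are kept.  Deterministic given the input.
#' Clusters are ordered by size descending (cluster 1 is the most
#' populated).
#'
#' @param sim non-negative symmetric similarity matrix.
#' @param inflation inflation exponent (default 2).
#' @param maxIter iteration cap.
#' @param tol convergence tolerance on the matrix change.
#' @param prune entries below this are zeroed each iteration.
#' @param stretch rescale off-diagonal similarities linearly onto [0, 1]
#'   before clustering (default TRUE).  Structural similarity scores live
#'   on a compressed scale (any two conformations of the same chain share
#'   most contact states), and flow-based clustering needs the contrast.
#' @return list \code{labels} (integer per model, 1 = largest cluster),
#'   \code{nClusters}, \code{medoids} (index of the model minimizing summed
#'   structural distance within each cluster, using \code{1 - sim}).
#' @export
mclCluster <- function(sim, inflation = 2, maxIter = 200L, tol = 1e-8,
                       prune = 1e-10, stretch = TRUE) {
  stopifnot(isSymmetric(unname(sim)), all(sim >= 0))
  n <- nrow(sim)
  if (stretch && n > 1L) {
    off <- sim[row(sim) != col(sim)]
    rng <- range(off)
    if (diff(rng) > 0) {
      sim <- (sim - rng[1L]) / diff(rng)
      sim[sim < 0] <- 0
      diag(sim) <- 1
    }
  }
  M <- sweep(sim, 2L, colSums(sim), `/`)
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, `/`)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                 maxIter, delta))
  ## attractors: rows with mass on the diagonal; each column joins the
  ## attractor row(s) it flows to
  attractors <- which(diag(M) > tol)
  comp <- rep(NA_integer_, n)
  groups <- list()
  for (a in attractors) {
    members <- which(M[a, ] > tol)
    hit <- which(vapply(groups, function(g) any(members %in% g), TRUE))
    if (length(hit)) {
      groups[[hit[1L]]] <- union(groups[[hit[1L]]], members)
      if (length(hit) > 1L) {
        for (h in rev(hit[-1L])) {
          groups[[hit[1L]]] <- union(groups[[hit[1L]]], groups[[h]])
          groups[[h]] <- NULL
        }
      }
    } else groups[[length(groups) + 1L]] <- members
  }
  for (g in seq_along(groups)) comp[groups[[g]]] <- g
  comp[is.na(comp)] <- seq(from = length(groups) + 1L,
                           length.out = sum(is.na(comp)))   # singletons
  ## order clusters by size descending
  sizes <- table(comp)
  newId <- rank(-as.numeric(sizes), ties.method = "first")
  labels <- as.integer(newId[match(comp, as.integer(names(sizes)))])
  dmat <- 1 - sim
  medoids <- vapply(seq_len(max(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(dmat[idx, idx, drop = FALSE]))]
  }, 1L)
  list(labels = labels, nClusters = max(labels), medoids = medoids)
}

## deterministic Fibonacci-spiral mesh on the unit sphere
.sphereMesh <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Particle accessibility
#'
#' For each particle, \code{nMesh} points are placed on a deterministic
#' Fibonacci spiral on the sphere of radius \code{radius + probeRadius}
#' around its centre; a point is accessible when no other particle centre
#' lies within \code{radius + probeRadius} of it.  Accessibility is the
#' percentage of accessible points.
#'
#' @param coords n x 3 model coordinates (nm).
#' @param radius particle radius (nm).
#' @param probeRadius probe radius (nm), default 75.
#' @param nMesh mesh points per particle (>= 50).
#' @return numeric vector, percentage in [0, 100] per particle.
#' @export
accessibility <- function(coords, radius, probeRadius = 75, nMesh = 100L) {
  stopifnot(probeRadius > 0, nMesh >= 50L)
  n <- nrow(coords)
  mesh <- .sphereMesh(nMesh) * (radius + probeRadius)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(mesh, 2L, coords[i, ], `+`)
    others <- coords[-i, , drop = FALSE]
    ## blocked if any other centre within radius + probeRadius of the point
    d2 <- outer(rowSums(pts^2), rowSums(others^2), `+`) -
      2 * pts %*% t(others)
    blocked <- rowSums(d2 < (radius + probeRadius)^2) > 0
    out[i] <- 100 * mean(!blocked)
  }
  out
}

#' Local chromatin density along the chain
#'
#' For particle i, the genomic span between particles \code{i - w} and
#' \code{i + w} (bp; windows clipped at the chain ends) divided by the
#' summed consecutive 3D distances along that sub-chain (nm).  A straight
#' chain of 10 kb particles spaced 100 nm has density 100 bp/nm everywhere.
#'
#' @param coords n x 3 coordinates (nm).
#' @param resolution bp per particle.
#' @param w window half-width in particles (default 3).
#' @return numeric vector, bp/nm per particle.
#' @export
chainDensity <- function(coords, resolution, w = 3L) {
  n <- nrow(coords)
  stopifnot(w >= 1L, w <= n %/% 2)
  step <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                        coords[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(step))
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    (hi - lo) * resolution / (cum[hi] - cum[lo])
  }, 0)
}

#' Interaction count per particle
#'
#' Number of other particles within \code{cutoff} nm; for an ensemble the
#' mean over models.
#'
#' @param x n x 3 coordinates, list of such, or a
#'   \code{\linkS4class{ModelEnsemble}}.
#' @param cutoff distance cutoff (nm), default 250.
#' @return numeric vector per particle.
#' @export
interactionCount <- function(x, cutoff = 250) {
  stopifnot(cutoff > 0)
  coordsList <- if (is(x, "ModelEnsemble")) x@coords
                else if (is.list(x)) x else list(x)
  counts <- vapply(coordsList, function(coords) {
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    rowSums(d < cutoff)
  }, numeric(nrow(coordsList[[1L]])))
  rowMeans(matrix(counts, nrow = nrow(coordsList[[1L]])))
}

#' Angle at each particle
#'
#' Angle (degrees, in [0, 180]) between the vectors from particle i to its
#' two chain neighbours; terminal particles get \code{NA}, as do particles
#' coincident with a neighbour (with a warning).
#'
#' @param coords n x 3 coordinates.
#' @return numeric vector of angles per particle.
#' @export
particleAngles <- function(coords) {
  n <- nrow(coords)
  stopifnot(n >= 3L)
  out <- rep(NA_real_, n)
  warned <- FALSE
  for (i in 2:(n - 1L)) {
    u <- coords[i - 1L, ] - coords[i, ]
    v <- coords[i + 1L, ] - coords[i, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) { warned <- TRUE; next }
    cosang <- max(-1, min(1, sum(u * v) / (nu * nv)))
    out[i] <- acos(cosang) * 180 / pi
  }
  if (warned) warning("coincident neighbour particles: angle undefined")
  out
}

CHROMATIN_COLORS <- c("black", "blue", "green", "yellow", "red")

#' Assign chromatin colors to particles
#'
#' Each particle's genomic bin is intersected with the color intervals (bp,
#' 0-based half-open); the particle takes a color when at least
#' \code{minCoverage} of the bin is covered by that color (ties at exactly
#' the threshold are assigned, and a tie between two qualifying colors goes
#' to the first in the canonical order black, blue, green, yellow, red);
#' otherwise it is the undefined \code{"white"}.
#'
#' @param binStarts,binEnds particle bin coordinates (bp, half-open).
#' @param colorBed data.frame \code{chrom, start, end, color} (colors in
#'   upper or lower case) or a BED file path.
#' @param chrom chromosome of the region.
#' @param minCoverage coverage threshold (default 0.5).
#' @return character vector of colors per particle.
#' @export
assignColors <- function(binStarts, binEnds, colorBed, chrom,
                         minCoverage = 0.5) {
  if (is.character(colorBed) && length(colorBed) == 1L)
    colorBed <- read.table(colorBed, sep = "\t",
                           col.names = c("chrom", "start", "end", "color"),
                           stringsAsFactors = FALSE)
  colorBed$color <- tolower(colorBed$color)
  colorBed <- colorBed[colorBed$chrom == chrom, , drop = FALSE]
  ## merge overlapping same-color intervals
  merged <- do.call(rbind, lapply(split(colorBed, colorBed$color), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)])) {
      warning("overlapping intervals of color ", df$color[1L], " merged")
      keep <- list(df[1L, ])
      for (r in 2:nrow(df)) {
        last <- keep[[length(keep)]]
        if (df$start[r] < last$end)
          keep[[length(keep)]]$end <- max(last$end, df$end[r])
        else keep[[length(keep) + 1L]] <- df[r, ]
      }
      df <- do.call(rbind, keep)
    }
    df
  }))
  vapply(seq_along(binStarts), function(b) {
    width <- binEnds[b] - binStarts[b]
    cov <- vapply(CHROMATIN_COLORS, function(cl) {
      iv <- merged[merged$color == cl, , drop = FALSE]
      if (!nrow(iv)) return(0)
      sum(pmax(0, pmin(iv$end, binEnds[b]) - pmax(iv$start, binStarts[b]))) / width
    }, 0)
    hit <- which(cov >= minCoverage)
    if (length(hit)) CHROMATIN_COLORS[hit[1L]] else "white"
  }, "")
}

#' Structural profile of an ensemble
#'
#' Per-particle accessibility, density, interactions and angle, averaged
#' over the models of the most populated cluster (or the whole ensemble).
#'
#' @param ensemble a \code{\linkS4class{ModelEnsemble}}.
#' @param radius particle radius (nm); taken from
#'   \code{ensemble@params$radius} when present.
#' @param cutoff interaction cutoff (nm).
#' @param probeRadius,nMesh accessibility parameters.
#' @param w density window.
#' @param cluster \code{"main"} (models of cluster 1, clustered at
#'   \code{dcutoff = cutoff}) or \code{"all"}.
#' @return data.frame \code{particle, accessibility, density, interactions,
#'   angle}.
#' @export
structuralProfile <- function(ensemble, radius = NULL, cutoff = 250,
                              probeRadius = 75, nMesh = 100L, w = 3L,
                              cluster = c("main", "all")) {
  cluster <- match.arg(cluster)
  if (is.null(radius)) radius <- ensemble@params$radius
  if (is.null(radius)) stop("particle radius required")
  resolution <- ensemble@params$resolution
  if (is.null(resolution)) resolution <- ensemble@region$resolution
  if (is.null(resolution)) stop("resolution required for density")
  coords <- ensemble@coords
  if (cluster == "main" && length(coords) > 2L) {
    sim <- similarityMatrix(coords, dcutoff = cutoff)
    cl <- mclCluster(sim)
    coords <- coords[cl$labels == 1L]
  }
  acc <- rowMeans(vapply(coords, accessibility, numeric(nrow(coords[[1L]])),
                         radius = radius, probeRadius = probeRadius,
                         nMesh = nMesh))
  den <- rowMeans(vapply(coords, chainDensity, numeric(nrow(coords[[1L]])),
                         resolution = resolution, w = w))
  int <- interactionCount(coords, cutoff)
  ang <- rowMeans(vapply(coords, particleAngles, numeric(nrow(coords[[1L]]))),
                  na.rm = TRUE)
  data.frame(particle = seq_len(nrow(coords[[1L]])), accessibility = acc,
             density = den, interactions = int, angle = ang)
}

#' Per-color distributions, medians and Tukey HSD tests
#'
#' Groups particle-level measures by chromatin color, reports medians per
#' color, and tests all color pairs per measure with Tukey's Honest
#' Significant Difference test (colors with fewer than 3 particles are
#' excluded from testing, with a note).
#'
#' @param profile data.frame from \code{\link{structuralProfile}} (or with
#'   the same measure columns).
#' @param colors character vector of colors per particle.
#' @param measures which columns to analyse.
#' @return list \code{medians} (color x measure matrix), \code{tukey}
#'   (named list of TukeyHSD tables per measure), \code{excluded}.
#' @export
profileByColor <- function(profile, colors,
                           measures = c("accessibility", "density",
                                        "interactions", "angle")) {
  colors <- factor(colors)
  tab <- table(colors)
  excluded <- names(tab)[tab < 3L]
  keepCl <- !(colors %in% excluded)
  if (length(unique(colors[keepCl])) < 2L)
    stop("need at least 2 colors with 3 or more particles")
  medians <- sapply(measures, function(m)
    tapply(profile[[m]], colors, median, na.rm = TRUE))
  tukey <- lapply(measures, function(m) {
    df <- data.frame(y = profile[[m]][keepCl],
                     g = droplevels(colors[keepCl]))
    df <- df[is.finite(df$y), ]
    TukeyHSD(aov(y ~ g, data = df))$g
  })
  names(tukey) <- measures
  list(medians = medians, tukey = tukey, excluded = excluded)
}
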