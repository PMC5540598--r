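## Restraint-based 3D modelling: z-scored contact frequencies, typed
## distance restraints, a simulated-annealing + quasi-Newton optimizer, and
## the grid search of modelling parameters by model-vs-input correlation.

#' Modelling parameters
#'
#' The tunable parameters of restraint-based modelling.  \code{scale}
#' converts genomic length to physical length (default 0.01 nm/bp, the
#' canonical 30 nm fibre), so a 10 kb particle has a 100 nm occupancy
#' (radius 50 nm).  \code{lowfreq}/\code{upfreq} are z-score cutoffs
#' separating non-interacting from frequently interacting particle pairs;
#' \code{maxdist} is the equilibrium distance of the weakest attractive
#' restraint and (by default) the proximal distance imposed on
#' non-interacting pairs; \code{dcutoff} is the distance below which two
#' particles of a model count as touching.
#'
#' @param resolution bp per particle.
#' @param scale nm per bp.
#' @param lowfreq,upfreq z-score cutoffs, \code{lowfreq <= upfreq}.
#' @param maxdist nm.
#' @param dcutoff nm; default \code{2 * maxdist / 3}.
#' @param kForce base force constant (per nm^2).
#' @param proximalDist nm; default \code{maxdist}.
#' @return named list of parameters.
#' @export
modelingParams <- function(resolution = 1e4, scale = 0.01, lowfreq = -0.6,
                           upfreq = 0.3, maxdist = 1500,
                           dcutoff = 2 * maxdist / 3, kForce = 0.05,
                           proximalDist = maxdist) {
  if (lowfreq > upfreq) stop("lowfreq must not exceed upfreq")
  if (scale <= 0) stop("scale must be positive")
  radius <- resolution * scale / 2
  if (maxdist <= 2 * radius)
    stop("maxdist must exceed the particle diameter (", 2 * radius, " nm)")
  list(resolution = resolution, scale = scale, lowfreq = lowfreq,
       upfreq = upfreq, maxdist = maxdist, dcutoff = dcutoff,
       kForce = kForce, proximalDist = proximalDist, radius = radius)
}

#' z-scores of log contact frequencies
#'
#' \code{z_ij = (log10 x_ij - mean) / sd} over unmasked, non-zero,
#' off-diagonal entries; zero or masked entries carry \code{NA} ("no data").
#' Doubling all counts shifts every log equally, so z is depth-invariant.
#'
#' @param mat single-region \code{\linkS4class{HiCMatrix}} or plain
#'   symmetric matrix.
#' @return symmetric matrix of z values with \code{NA} where no data.
#' @export
zscoreMatrix <- function(mat) {
  if (is(mat, "HiCMatrix")) {
    counts <- mat@counts
    keep <- unmaskedIdx(mat)
    unmask <- logical(nrow(counts)); unmask[keep] <- TRUE
  } else {
    counts <- unname(as.matrix(mat))
    unmask <- rep(TRUE, nrow(counts))
  }
  n <- nrow(counts)
  use <- outer(unmask, unmask) & counts > 0 & row(counts) != col(counts)
  if (sum(use[upper.tri(use)]) < 10L)
    stop("insufficient data: fewer than 10 non-zero entries")
  lx <- log10(counts[use])
  mu <- mean(lx); s <- sd(lx)
  z <- matrix(NA_real_, n, n)
  if (s == 0) {
    warning("zero variance in log frequencies; all z set to 0")
    z[use] <- 0
  } else {
    z[use] <- (log10(counts[use]) - mu) / s
  }
  z
}

#' Build spatial restraints from a z-score matrix
#'
#' Consecutive particles are restrained harmonically at the sum of their
#' radii (their occupancy).  Non-consecutive pairs with \code{z >= upfreq}
#' get an attractive harmonic at \code{d(z)}, the linear decreasing map of
#' the observed z range onto \code{[2 * radius, maxdist]} (the boundary
#' z = upfreq is attractive); pairs with \code{z <= lowfreq} get a
#' lower-bound harmonic at the proximal distance; all remaining pairs get a
#' soft excluded-volume lower bound at one particle diameter.  z-derived
#' force constants are weighted by |z| (stronger evidence, stiffer
#' restraint).
#'
#' @param z matrix from \code{\link{zscoreMatrix}}.
#' @param params list from \code{\link{modelingParams}}.
#' @return a \code{\linkS4class{RestraintSet}}.
#' @export
buildRestraints <- function(z, params = modelingParams()) {
  n <- nrow(z)
  r <- params$radius
  zz <- z[upper.tri(z)]
  zmin <- suppressWarnings(min(zz, na.rm = TRUE))
  zmax <- suppressWarnings(max(zz, na.rm = TRUE))
  dz <- function(zv) {
    if (!is.finite(zmin) || zmax == zmin) return(rep((2 * r + params$maxdist) / 2, length(zv)))
    params$maxdist - (zv - zmin) / (zmax - zmin) * (params$maxdist - 2 * r)
  }
  ut <- which(upper.tri(z), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  zv <- z[ut]
  kind <- character(length(i)); d0 <- numeric(length(i)); k <- numeric(length(i))
  consec <- j == i + 1L
  kind[consec] <- "harmonic"; d0[consec] <- 2 * r; k[consec] <- params$kForce
  attr_ <- !consec & !is.na(zv) & zv >= params$upfreq
  kind[attr_] <- "harmonic"; d0[attr_] <- dz(zv[attr_])
  k[attr_] <- params$kForce * abs(zv[attr_])
  rep_ <- !consec & !is.na(zv) & zv <= params$lowfreq
  kind[rep_] <- "lower"; d0[rep_] <- params$proximalDist
  k[rep_] <- params$kForce * abs(zv[rep_])
  ev <- kind == ""
  kind[ev] <- "lower"; d0[ev] <- 2 * r; k[ev] <- params$kForce / 10
  new("RestraintSet", i = as.integer(i), j = as.integer(j), kind = kind,
      dist = d0, k = k, radius = r, nParticles = as.integer(n))
}

.kindCode <- function(kind) match(kind, c("harmonic", "lower", "upper")) - 1L

#' Objective value of a coordinate set under a restraint set
#'
#' @param coords n x 3 matrix (nm).
#' @param restraints a \code{\linkS4class{RestraintSet}}.
#' @return total harmonic penalty.
#' @export
restraintObjective <- function(coords, restraints) {
  .objectiveCpp(coords, restraints@i, restraints@j,
                .kindCode(restraints@kind), restraints@dist, restraints@k)
}

#' Optimize one model
#'
#' Seeded random start uniform in a sphere of radius
#' \code{n^(1/3) * 2 * radius}, simulated annealing (default 500 sweeps,
#' geometric temperature 10 to 0.01) with single-particle moves, then a
#' deterministic L-BFGS-B polish using the closed-form gradient.
#' Deterministic given \code{seed}; a non-finite objective triggers up to 3
#' restarts with perturbed seeds before failing.
#'
#' @param restraints a \code{\linkS4class{RestraintSet}}.
#' @param seed integer RNG seed.
#' @param nSweeps annealing sweeps.
#' @param tStart,tEnd annealing temperature schedule.
#' @return list \code{coords} (n x 3), \code{objective}, \code{seed}.
#' @export
optimizeModel <- function(restraints, seed, nSweeps = 500L, tStart = 10,
                          tEnd = 0.01) {
  n <- restraints@nParticles
  ri <- restraints@i; rj <- restraints@j
  kc <- .kindCode(restraints@kind); d0 <- restraints@dist; kk <- restraints@k
  fn <- function(x) .objectiveCpp(matrix(x, ncol = 3L), ri, rj, kc, d0, kk)
  gr <- function(x) as.vector(.gradientCpp(matrix(x, ncol = 3L), ri, rj, kc, d0, kk))
  for (attempt in 0:3) {
    set.seed(seed + attempt * 1000003L)
    R0 <- n^(1/3) * 2 * restraints@radius
    u <- matrix(rnorm(3 * n), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    coords <- u * (R0 * runif(n)^(1/3))
    coords <- .annealCpp(coords, ri, rj, kc, d0, kk,
                         as.integer(nSweeps), tStart, tEnd,
                         restraints@radius / 2)
    fit <- optim(as.vector(coords), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = 500L))
    if (is.finite(fit$value))
      return(list(coords = matrix(fit$par, ncol = 3L),
                  objective = fit$value, seed = seed))
  }
  stop("optimization produced a non-finite objective after 3 restarts")
}

#' Generate an ensemble of models
#'
#' Runs \code{nCompute} independent seeded optimizations (seeds
#' \code{baseSeed, baseSeed + 1, ...}) and keeps the \code{nKeep} best by
#' objective, sorted ascending.  Bit-identical given \code{baseSeed}.
#'
#' @param restraints a \code{\linkS4class{RestraintSet}}.
#' @param nCompute,nKeep models computed / kept (production defaults
#'   2500/2000; use small values for exploration).
#' @param baseSeed integer seed.
#' @param region optional named list (chrom, start, end, resolution).
#' @param params the modelling parameter list (stored for provenance).
#' @param ... passed to \code{\link{optimizeModel}}.
#' @return a \code{\linkS4class{ModelEnsemble}}.
#' @export
generateEnsemble <- function(restraints, nCompute = 2500L, nKeep = 2000L,
                             baseSeed = 1L, region = list(), params = list(),
                             ...) {
  if (nKeep > nCompute) stop("nKeep must not exceed nCompute")
  models <- lapply(seq_len(nCompute) - 1L, function(k)
    optimizeModel(restraints, baseSeed + k, ...))
  objs <- vapply(models, `[[`, 0, "objective")
  ord <- order(objs)[seq_len(nKeep)]
  new("ModelEnsemble",
      coords = lapply(models[ord], `[[`, "coords"),
      objectives = objs[ord],
      seeds = as.integer(baseSeed + ord - 1L),
      region = region, params = params)
}

#' Contact map of a model ensemble
#'
#' Entry (i, j) is the fraction of models in which particles i and j lie
#' closer than \code{dcutoff} nm; symmetric with unit diagonal.
#'
#' @param ensemble a \code{\linkS4class{ModelEnsemble}} or list of n x 3
#'   matrices.
#' @param dcutoff contact distance (nm).
#' @return symmetric matrix of contact fractions in [0, 1].
#' @export
modelContactMap <- function(ensemble, dcutoff) {
  coords <- if (is(ensemble, "ModelEnsemble")) ensemble@coords else ensemble
  stopifnot(length(coords) >= 1L)
  .contactMapCpp(coords, dcutoff)
}

#' Correlation of a model contact map with the input matrix
#'
#' Spearman correlation over off-diagonal upper-triangle cells with data in
#' the input.
#'
#' @param cmap contact-fraction matrix.
#' @param input observed matrix (same size).
#' @return Spearman rho.
#' @export
mapInputCorrelation <- function(cmap, input) {
  input <- if (is(input, "HiCMatrix")) input@counts else unname(as.matrix(input))
  sel <- upper.tri(input) & !is.na(input)
  cor(cmap[sel], input[sel], method = "spearman")
}

#' Grid search of the modelling parameters
#'
#' For every combination of \code{lowfreq}, \code{upfreq} (keeping
#' \code{lowfreq <= upfreq}) and \code{maxdist}, builds \code{nSmall} models
#' and scores the Spearman correlation between their contact map (at
#' \code{dcutoff = 2 * maxdist / 3} unless given) and the input matrix;
#' returns the best parameter set and the full correlation table.
#'
#' @param input region matrix (plain symmetric or \code{HiCMatrix}).
#' @param lowfreq,upfreq,maxdist grid vectors.
#' @param dcutoff optional fixed contact cutoff (nm).
#' @param nSmall models per grid point (>= 10).
#' @param resolution bp per particle.
#' @param baseSeed seed for every grid point's ensemble.
#' @param ... passed to \code{\link{generateEnsemble}}.
#' @return list \code{best} (params list), \code{bestCorrelation},
#'   \code{table} (data.frame of all grid points).
#' @export
optimizeParams <- function(input, lowfreq = c(-1.2, -0.6, 0),
                           upfreq = c(0, 0.6, 1.2),
                           maxdist = c(1000, 1500, 2000),
                           dcutoff = NULL, nSmall = 50L,
                           resolution = 1e4, baseSeed = 1L, ...) {
  if (nSmall < 10L) stop("nSmall must be at least 10")
  z <- zscoreMatrix(input)
  grid <- expand.grid(lowfreq = lowfreq, upfreq = upfreq, maxdist = maxdist)
  grid <- grid[grid$lowfreq <= grid$upfreq, , drop = FALSE]
  if (nrow(grid) == 0L) stop("empty parameter grid")
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    p <- modelingParams(resolution = resolution,
                        lowfreq = grid$lowfreq[g], upfreq = grid$upfreq[g],
                        maxdist = grid$maxdist[g],
                        dcutoff = if (is.null(dcutoff)) 2 * grid$maxdist[g] / 3 else dcutoff)
    res <- try({
      rs <- buildRestraints(z, p)
      ens <- generateEnsemble(rs, nCompute = nSmall, nKeep = nSmall,
                              baseSeed = baseSeed, params = p, ...)
      cm <- modelContactMap(ens, p$dcutoff)
      mapInputCorrelation(cm, input)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(grid[g, ], dcutoff = NA_real_, correlation = NA_real_,
                 error = as.character(res))
    else
      data.frame(grid[g, ], dcutoff = p$dcutoff, correlation = res,
                 error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(is.na(tab$correlation)))
    stop("all grid points failed:\n", paste(tab$error, collapse = "\n"))
  bestIdx <- which.max(tab$correlation)
  best <- modelingParams(resolution = resolution,
                         lowfreq = tab$lowfreq[bestIdx],
                         upfreq = tab$upfreq[bestIdx],
                         maxdist = tab$maxdist[bestIdx],
                         dcutoff = tab$dcutoff[bestIdx])
  list(best = best, bestCorrelation = tab$correlation[bestIdx], table = tab)
}

#' Write / read model coordinates as XYZ text
#'
#' One row per particle: \code{particle_index chrom:start-end x y z} (nm).
#'
#' @param ensemble a \code{\linkS4class{ModelEnsemble}}.
#' @param dir output directory (one file per model,
#'   \code{model_<rank>.xyz}) plus \code{manifest.json} with params, seeds
#'   and objectives.
#' @export
writeEnsembleXyz <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- ensemble@region
  lab <- if (length(reg))
    sprintf("%s:%g-%g", reg$chrom,
            reg$start + (seq_len(nrow(ensemble@coords[[1L]])) - 1L) * reg$resolution,
            reg$start + seq_len(nrow(ensemble@coords[[1L]])) * reg$resolution)
  else as.character(seq_len(nrow(ensemble@coords[[1L]])))
  for (m in seq_along(ensemble@coords)) {
    df <- data.frame(seq_len(nrow(ensemble@coords[[m]])), lab,
                     ensemble@coords[[m]])
    write.table(df, file.path(dir, sprintf("model_%04d.xyz", m)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  jsonlite::write_json(list(nModels = length(ensemble@coords),
                            objectives = ensemble@objectives,
                            seeds = ensemble@seeds,
                            region = ensemble@region,
                            params = ensemble@params),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
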