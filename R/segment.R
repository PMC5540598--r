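## Chromosome segmentation into TADs: dynamic programming over change
## points under a BIC-penalized Poisson likelihood, with a 1-10 border
## robustness score and per-TAD intra-density flags.
##
## Model: expected count at distance d is the mean unmasked count at that
## distance (distance-decay expectation, refit per input matrix); within a
## candidate TAD [i..j] counts are Poisson(w * e_ij) with segment intensity
## w estimated by maximum likelihood (w = sum(obs)/sum(exp) over the
## intra-TAD triangle).  The constant log(obs!) terms cancel across
## segmentations and are dropped.

#' Distance-decay expectation of a single-region matrix
#'
#' @param counts symmetric numeric matrix.
#' @param unmask logical vector, TRUE for usable bins.
#' @return matrix of expected counts; \code{NA} where no usable cells exist
#'   at that distance (or the mean is zero).
#' @export
decayExpectation <- function(counts, unmask = rep(TRUE, nrow(counts))) {
  n <- nrow(counts)
  E <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    ok <- unmask[i] & unmask[i + d]
    if (!any(ok)) next
    m <- mean(counts[cbind(i[ok], i[ok] + d)])
    if (m > 0) {
      E[cbind(i[ok], i[ok] + d)] <- m
      E[cbind(i[ok] + d, i[ok])] <- m
    }
  }
  E
}

#' Log-likelihood score of one candidate TAD
#'
#' Direct evaluation of the segment score: with observed counts \code{obs}
#' and expectations \code{expected} over the intra-segment triangle
#' (\code{i <= a <= b <= j}, usable cells only), the maximum-likelihood
#' intensity is \code{w = sum(obs)/sum(exp)} and the score is the Poisson
#' log-likelihood improvement of that intensity over the distance-decay
#' baseline (w = 1): \code{So * log(w) - (w - 1) * Se} with
#' \code{So = sum(obs)}, \code{Se = sum(exp)} (the \code{log(obs!)} terms
#' cancel in the ratio).  A segment whose counts equal the expectation
#' scores 0; the score is never negative at the MLE, and cells outside
#' every TAD contribute the same baseline under any segmentation, so
#' segmentations of different sizes are compared on equal footing.
#'
#' @param counts symmetric matrix of (normalized) counts.
#' @param expected matrix from \code{\link{decayExpectation}} (\code{NA} =
#'   unusable cell).
#' @param i,j 1-based segment bounds, \code{i <= j}.
#' @return scalar score (0 for a segment without usable signal).
#' @export
segmentScore <- function(counts, expected, i, j) {
  if (i > j || i < 1L || j > nrow(counts))
    stop("invalid segment [", i, ", ", j, "]")
  sel <- which(upper.tri(matrix(0, j - i + 1L, j - i + 1L), diag = TRUE),
               arr.ind = TRUE)
  a <- sel[, 1L] + i - 1L; b <- sel[, 2L] + i - 1L
  e <- expected[cbind(a, b)]
  o <- counts[cbind(a, b)]
  use <- !is.na(e)
  So <- sum(o[use]); Se <- sum(e[use])
  if (Se <= 0) return(0)
  if (So <= 0) return(Se)              # w = 0 beats baseline by Se
  w <- So / Se
  So * log(w) - (w - 1) * Se
}

## Prefix-sum machinery: triangle sums of a symmetric matrix in O(1).
.prefix <- function(M) {
  n <- nrow(M)
  P <- matrix(0, n + 1L, n + 1L)
  P[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum)
  t(P)
}
.rectSum <- function(P, i1, i2, j1, j2)  # vectorised over any argument
  P[cbind(i2 + 1L, j2 + 1L)] - P[cbind(i1, j2 + 1L)] -
  P[cbind(i2 + 1L, j1)] + P[cbind(i1, j1)]

.triSums <- function(M) {
  ## returns closure tri(i, j) = sum over i<=a<=b<=j of M[a,b]
  P <- .prefix(M)
  dcum <- c(0, cumsum(diag(M)))
  function(i, j) (.rectSum(P, i, j, i, j) + (dcum[j + 1L] - dcum[i])) / 2
}

## decay expectation restricted to cross-TAD cells (background refit);
## distances with too few cross cells keep the pooled estimate
.decayFromInter <- function(counts, unmask, borders, minCells = 5L) {
  n <- nrow(counts)
  tad <- findInterval(seq_len(n), borders)
  pooled <- decayExpectation(counts, unmask)
  E <- pooled
  for (d in 1:(n - 1L)) {
    i <- seq_len(n - d)
    ok <- unmask[i] & unmask[i + d]
    cross <- ok & tad[i] != tad[i + d]
    if (sum(cross) < minCells) next
    m <- mean(counts[cbind(i[cross], i[cross] + d)])
    if (m > 0) {
      all_ok <- which(ok)
      E[cbind(all_ok, all_ok + d)] <- m
      E[cbind(all_ok + d, all_ok)] <- m
    }
  }
  E
}

.segmentEngine <- function(counts, unmask, maxTadBins, minTadBins,
                           E = NULL, enrichedOnly = FALSE) {
  n <- nrow(counts)
  if (is.null(E)) E <- decayExpectation(counts, unmask)
  use <- !is.na(E)
  O <- ifelse(use, counts, 0)
  Ee <- ifelse(use, E, 0)
  triO <- .triSums(O); triE <- .triSums(Ee)
  score <- function(i, j) {
    So <- triO(i, j); Se <- triE(i, j)
    out <- ifelse(Se <= 0, 0,
                  ifelse(So <= 0, Se,
                         So * log(pmax(So, 1e-300) / pmax(Se, 1e-300)) -
                           (So - Se)))
    ## one-sided mode: only enrichment (w >= 1) counts as TAD signal, so
    ## depleted pockets cannot be harvested as spurious micro-domains
    if (enrichedOnly) out <- ifelse(So <= Se, 0, out)
    out
  }
  ## score matrix S[i, j] for allowed segment lengths, else -Inf
  S <- matrix(-Inf, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - maxTadBins + 1L)
    hi <- j - minTadBins + 1L
    if (hi < lo) next
    i <- lo:hi
    S[i, j] <- score(i, j)
  }
  Tcells <- sum(use[upper.tri(E, diag = TRUE)])
  list(S = S, E = E, Tcells = max(Tcells, 2L), n = n)
}

.maskedRunOk <- function(unmask, maxMaskedRun) {
  ## TRUE where a TAD may start: not inside a run of >= maxMaskedRun masked bins
  n <- length(unmask)
  ok <- rep(TRUE, n)
  r <- rle(!unmask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= maxMaskedRun)
      ok[starts[k]:ends[k]] <- FALSE
  ok[1L] <- TRUE
  ok
}

#' Optimal TAD segmentation of a chromosome matrix
#'
#' Dynamic program over (last border, number of TADs): for each m the best
#' total segment log-likelihood L(m) is computed exactly, and the returned
#' segmentation maximizes \code{L(m) - bicMult * (2m-1)/2 * log(T)} where T
#' is the number of usable upper-triangle cells (one intensity parameter per
#' TAD plus one per internal border).  Border robustness (1-10) counts in how
#' many of the constrained-optimal segmentations with m*, m*+1, ..., m*+9
#' TADs the border persists at the same bin.  The input is canonically
#' rescaled to a reference mean count so segmentation depends on relative
#' enrichment rather than sequencing depth (disable with
#' \code{rescale = FALSE}).
#'
#' @param mat single-chromosome \code{\linkS4class{HiCMatrix}}, or a plain
#'   symmetric matrix (then \code{resolution}/\code{chrom} label the output).
#' @param maxTadBins,minTadBins largest/smallest allowed TAD in bins.
#' @param bicMult multiplier on the BIC penalty.
#' @param forceM force exactly this number of TADs instead of the BIC
#'   optimum.
#' @param maxMaskedRun a border may not sit inside a run of at least this
#'   many consecutive masked bins.
#' @param rescale,referenceMean canonical rescaling of the mean unmasked
#'   count (scale invariance of the segmentation).
#' @param refinePasses background-refit iterations: after a first pass on
#'   the pooled distance-decay expectation, the background is re-estimated
#'   from cross-TAD cells only and the program re-run (the pooled fit is
#'   contaminated by intra-TAD enrichment).
#' @param resolution,chrom used when \code{mat} is a plain matrix.
#' @return a \code{\linkS4class{TadSegmentation}}.
#' @export
optimalSegmentation <- function(mat, maxTadBins = 300L, minTadBins = 2L,
                                bicMult = 1, forceM = NULL,
                                maxMaskedRun = 5L, rescale = TRUE,
                                referenceMean = 10, refinePasses = 2L,
                                resolution = NULL, chrom = NULL) {
  if (is(mat, "HiCMatrix")) {
    if (length(mat@chromNames) != 1L)
      stop("segmentation expects a single-chromosome matrix")
    if (!mat@normalized)
      warning("segmenting a non-normalized matrix")
    counts <- mat@counts
    unmask <- rep(FALSE, nrow(counts)); unmask[unmaskedIdx(mat)] <- TRUE
    resolution <- mat@resolution
    chrom <- mat@chromNames
  } else {
    counts <- unname(as.matrix(mat))
    unmask <- colSums(counts) > 0
    if (all(!unmask)) stop("matrix has no signal")
    if (is.null(resolution)) resolution <- 1
    if (is.null(chrom)) chrom <- "region"
  }
  n <- nrow(counts)
  if (rescale) {
    cells <- counts[unmask, unmask]
    mu <- mean(cells)
    if (mu > 0) counts <- counts * (referenceMean / mu)
  }
  if (n < 2L * minTadBins) {
    return(new("TadSegmentation", borders = 1L, strengths = 10L,
               densityRatio = 1, densityFlag = "higher",
               logLik = 0, nBins = as.integer(n),
               resolution = resolution, chrom = chrom))
  }
  okStart <- .maskedRunOk(unmask, maxMaskedRun)
  runDP <- function(E, enrichedOnly = FALSE) {
    eng <- .segmentEngine(counts, unmask, maxTadBins, minTadBins, E,
                          enrichedOnly)
    S <- eng$S
    mMax <- min(n %/% minTadBins, n)
    ## DP tables: L[m, j] best score of bins 1..j in m segments; back-pointers
    L <- matrix(-Inf, mMax, n)
    B <- matrix(NA_integer_, mMax, n)
    L[1L, ] <- S[1L, ]
    B[1L, !is.infinite(S[1L, ])] <- 1L
    for (m in 2:mMax) {
      prev <- L[m - 1L, ]
      for (j in seq_len(n)) {
        lo <- max(2L, j - maxTadBins + 1L)   # i = 1 would leave no prefix
        hi <- j - minTadBins + 1L
        if (hi < lo) next
        i <- lo:hi
        cand <- prev[i - 1L] + S[i, j]
        cand[!okStart[i]] <- -Inf
        if (all(is.infinite(cand))) next
        best <- which.max(cand)
        L[m, j] <- cand[best]
        B[m, j] <- i[best]
      }
      if (all(is.infinite(L[m, ]))) {
        mMax <- m - 1L
        L <- L[1:mMax, , drop = FALSE]; B <- B[1:mMax, , drop = FALSE]
        break
      }
    }
    feasible <- which(is.finite(L[, n]))
    if (!length(feasible)) stop("no feasible segmentation under the constraints")
    pen <- function(m) bicMult * (2 * m - 1) / 2 * log(eng$Tcells)
    scoreM <- L[feasible, n] - vapply(feasible, pen, 0)
    mStar <- if (is.null(forceM)) feasible[which.max(scoreM)] else {
      if (!forceM %in% feasible) stop("forceM = ", forceM, " is not feasible")
      as.integer(forceM)
    }
    traceBorders <- function(m) {
      b <- integer(m); j <- n
      for (mm in m:1) { b[mm] <- B[mm, j]; j <- B[mm, j] - 1L }
      b
    }
    borders <- traceBorders(mStar)
    ms <- intersect(mStar:(mStar + 9L), feasible)
    inM <- vapply(ms, function(m) borders %in% traceBorders(m),
                  logical(length(borders)))
    strengths <- as.integer(pmin(10L, pmax(1L, rowSums(matrix(inM,
      nrow = length(borders))))))
    list(borders = borders, strengths = strengths, eng = eng,
         logLik = unname(L[mStar, n] - pen(mStar)))
  }
  ## first pass on the pooled decay, then refine the background from
  ## cross-TAD cells only (the pooled fit is contaminated by intra-TAD
  ## enrichment, which flattens the contrast)
  res <- runDP(NULL)
  for (pass in seq_len(refinePasses)) {
    if (length(res$borders) < 2L) break
    E2 <- .decayFromInter(counts, unmask, res$borders)
    res2 <- runDP(E2, enrichedOnly = TRUE)
    same <- identical(res2$borders, res$borders)
    res <- res2
    if (same) break
  }
  borders <- res$borders
  strengths <- res$strengths
  ## per-TAD intra-density
  spans <- cbind(borders, c(borders[-1L] - 1L, n))
  E <- res$eng$E
  ratio <- apply(spans, 1L, function(sp) {
    i <- sp[1L]; j <- sp[2L]
    sel <- which(upper.tri(matrix(0, j - i + 1L, j - i + 1L), diag = TRUE),
                 arr.ind = TRUE)
    a <- sel[, 1L] + i - 1L; b <- sel[, 2L] + i - 1L
    e <- E[cbind(a, b)]; o <- counts[cbind(a, b)]
    use <- !is.na(e)
    if (!any(use) || sum(e[use]) == 0) return(1)
    sum(o[use]) / sum(e[use])
  })
  new("TadSegmentation", borders = as.integer(borders),
      strengths = strengths,
      densityRatio = as.numeric(ratio),
      densityFlag = ifelse(ratio >= 1, "higher", "lower"),
      logLik = res$logLik,
      nBins = as.integer(n), resolution = resolution, chrom = chrom)
}

#' Intra-TAD density of a span
#'
#' Mean observed/expected ratio over the intra-TAD triangle and the
#' higher/lower flag (\code{"higher"} when the ratio is at least 1).
#'
#' @param counts symmetric matrix.
#' @param i,j TAD bounds in bins.
#' @param unmask logical usable-bin vector.
#' @return list \code{ratio}, \code{flag}.
#' @export
intraTadDensity <- function(counts, i, j, unmask = rep(TRUE, nrow(counts))) {
  E <- decayExpectation(counts, unmask)
  sel <- which(upper.tri(matrix(0, j - i + 1L, j - i + 1L), diag = TRUE),
               arr.ind = TRUE)
  a <- sel[, 1L] + i - 1L; b <- sel[, 2L] + i - 1L
  e <- E[cbind(a, b)]; o <- counts[cbind(a, b)]
  use <- !is.na(e)
  ratio <- if (!any(use) || sum(e[use]) == 0) 1 else sum(o[use]) / sum(e[use])
  list(ratio = ratio, flag = if (ratio >= 1) "higher" else "lower")
}

#' Write TAD borders as a BED-like TSV
#'
#' One row per TAD: \code{chrom start end border_bin strength density_flag}
#' with 0-based half-open bp coordinates.
#'
#' @param seg a \code{\linkS4class{TadSegmentation}}.
#' @param path output file.
#' @export
writeBorders <- function(seg, path) {
  b <- seg@borders
  ends <- c(b[-1L] - 1L, seg@nBins)
  df <- data.frame(chrom = seg@chrom,
                   start = format((b - 1L) * seg@resolution, scientific = FALSE,
                                  trim = TRUE),
                   end = format(ends * seg@resolution, scientific = FALSE,
                                trim = TRUE),
                   border_bin = b,
                   strength = seg@strengths,
                   density_flag = seg@densityFlag)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a border list (bp positions) from a BED-like TSV
#'
#' Accepts the \code{\link{writeBorders}} output or any BED whose second
#' column is the border start position in bp.
#'
#' @param path input file.
#' @return numeric vector of border positions (bp, ascending).
#' @export
readBorderBed <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  sort(as.numeric(df[[2L]]))
}
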