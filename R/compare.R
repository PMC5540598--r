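## Replicate comparison of normalized matrices: per-genomic-distance
## Spearman correlation and Pearson correlation of leading eigenvectors.

#' Spearman correlation per genomic distance
#'
#' For each distance d in bins, the Spearman rank correlation between
#' \code{A[i, i+d]} and \code{B[i, i+d]} over all i with both bins unmasked
#' in both matrices (masks are unioned).  Distances with fewer than 3 usable
#' pairs or zero variance are reported \code{NA}.  All chromosomes are
#' pooled by default (genome-wide behaviour); set \code{chrom} to restrict.
#'
#' @param A,B \code{\linkS4class{HiCMatrix}} objects of identical shape.
#' @param maxDist maximum distance in bins.
#' @param chrom optional chromosome name to restrict to.
#' @return numeric vector of rho values indexed by distance 1..maxDist.
#' @export
spearmanByDistance <- function(A, B, maxDist, chrom = NULL) {
  if (!identical(dim(A@counts), dim(B@counts)))
    stop("matrices are incompatible: different shape")
  keep <- setdiff(seq_len(nrow(A@counts)), union(A@mask, B@mask))
  if (!is.null(chrom)) {
    rng <- chromBinRange(A, chrom)
    keep <- intersect(keep, seq(rng[1L], rng[2L]))
  }
  inKeep <- logical(nrow(A@counts)); inKeep[keep] <- TRUE
  vapply(seq_len(maxDist), function(d) {
    i <- seq_len(nrow(A@counts) - d)
    ok <- inKeep[i] & inKeep[i + d]
    a <- A@counts[cbind(i[ok], i[ok] + d)]
    b <- B@counts[cbind(i[ok], i[ok] + d)]
    if (length(a) < 3L || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }, 0)
}

chromBinRange <- function(mat, chrom) {
  k <- match(chrom, mat@chromNames)
  if (is.na(k)) stop("unknown chromosome: ", chrom)
  nb <- ceiling(mat@chromLengths / mat@resolution)
  start <- mat@offsets[[chrom]] + 1L
  c(start, start + nb[k] - 1L)
}

#' Leading eigenvectors of a contact matrix
#'
#' Eigen-decomposition of the symmetric matrix restricted to unmasked bins,
#' returning the top-k vectors by absolute eigenvalue, re-expanded to full
#' length with \code{NA} at masked bins.  The sign of each vector is fixed
#' by making its largest-magnitude entry positive, so results are
#' reproducible across linear-algebra backends.
#'
#' @param mat a \code{\linkS4class{HiCMatrix}} (normally ICE-normalized).
#' @param k number of leading eigenvectors.
#' @return list with \code{vectors} (n x k matrix, NA at masked bins) and
#'   \code{values} (length k).
#' @export
leadingEigenvectors <- function(mat, k = 3L) {
  keep <- unmaskedIdx(mat)
  M <- mat@counts[keep, keep, drop = FALSE]
  e <- eigen(M, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  if (k > length(ord)) {
    warning("requested ", k, " eigenvectors, matrix rank allows ", length(ord))
    k <- length(ord)
  }
  sel <- ord[seq_len(k)]
  V <- e$vectors[, sel, drop = FALSE]
  for (c in seq_len(ncol(V))) {
    big <- which.max(abs(V[, c]))
    if (V[big, c] < 0) V[, c] <- -V[, c]
  }
  full <- matrix(NA_real_, nrow(mat@counts), k)
  full[keep, ] <- V
  list(vectors = full, values = e$values[sel])
}

#' Pearson correlation of leading eigenvectors of two matrices
#'
#' Entry (p, q) is the absolute Pearson correlation between eigenvector p of
#' A and eigenvector q of B, computed on the intersection of unmasked bins
#' (eigenvector sign being arbitrary, absolute values are reported).
#'
#' @param A,B \code{\linkS4class{HiCMatrix}} objects.
#' @param k number of leading eigenvectors of each.
#' @return k x k matrix of |Pearson| values.
#' @export
eigenCorrelation <- function(A, B, k = 3L) {
  if (!identical(dim(A@counts), dim(B@counts)))
    stop("matrices are incompatible: different shape")
  ea <- leadingEigenvectors(A, k)
  eb <- leadingEigenvectors(B, k)
  keep <- which(stats::complete.cases(cbind(ea$vectors, eb$vectors)))
  out <- matrix(NA_real_, ncol(ea$vectors), ncol(eb$vectors))
  for (p in seq_len(ncol(ea$vectors)))
    for (q in seq_len(ncol(eb$vectors)))
      out[p, q] <- abs(cor(ea$vectors[keep, p], eb$vectors[keep, q]))
  out
}
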