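## Binned contact matrices: construction from valid pairs, sparse-column
## masking by the first-mode rule, truncated ICE balancing, merging, and
## text I/O (dense with header comments, or bin_i/bin_j/count triplets).

#' Construct an empty HiCMatrix
#'
#' @param chromLengths named numeric vector (bp) in genome order.
#' @param resolution bin size (bp).
#' @return a \code{\linkS4class{HiCMatrix}} of zeros.
#' @export
emptyHiCMatrix <- function(chromLengths, resolution) {
  nb <- ceiling(chromLengths / resolution)
  n <- sum(nb)
  offsets <- setNames(cumsum(c(0, nb[-length(nb)])), names(chromLengths))
  new("HiCMatrix", counts = matrix(0, n, n), resolution = resolution,
      chromNames = names(chromLengths), chromLengths = unname(chromLengths),
      offsets = offsets, mask = integer(), biases = numeric(),
      normalized = FALSE)
}

#' Genome-wide bin index of positions
#'
#' @param mat a \code{\linkS4class{HiCMatrix}}.
#' @param chrom,pos chromosome names and 0-based positions.
#' @return 1-based genome-wide bin indices.
#' @export
binIndex <- function(mat, chrom, pos) {
  off <- mat@offsets[chrom]
  lens <- setNames(mat@chromLengths, mat@chromNames)[chrom]
  if (anyNA(off)) stop("unknown chromosome in pair: ",
                       paste(unique(chrom[is.na(off)]), collapse = ", "))
  if (any(pos < 0 | pos >= lens)) {
    bad <- which(pos < 0 | pos >= lens)[1L]
    stop(sprintf("pair position %s:%g beyond chromosome end", chrom[bad], pos[bad]))
  }
  as.integer(off + floor(pos / mat@resolution) + 1)
}

#' Bin valid pairs into a contact matrix
#'
#' \code{counts[i,j]} is the number of pairs with one end in bin i and the
#' other in bin j (half-open binning, genome-wide indexing via chromosome
#' offsets).  Total pair count is conserved.
#'
#' @param pairs valid pairs data.frame (see \code{\link{applyFilters}}).
#' @param chromLengths named numeric vector (bp) in genome order.
#' @param resolution bin size (bp).
#' @return raw \code{\linkS4class{HiCMatrix}}.
#' @export
binPairs <- function(pairs, chromLengths, resolution) {
  mat <- emptyHiCMatrix(chromLengths, resolution)
  if (nrow(pairs)) {
    i <- binIndex(mat, pairs$chrom1, pairs$pos1)
    j <- binIndex(mat, pairs$chrom2, pairs$pos2)
    n <- nrow(mat@counts)
    tab <- table(factor((pmin(i, j) - 1L) * n + pmax(i, j)))
    idx <- as.integer(names(tab))
    lo <- (idx - 1L) %/% n + 1L
    hi <- (idx - 1L) %% n + 1L
    cts <- mat@counts
    cts[cbind(lo, hi)] <- cts[cbind(lo, hi)] + as.numeric(tab)
    cts[cbind(hi, lo)] <- cts[cbind(lo, hi)]
    mat@counts <- cts
  }
  validObject(mat)
  mat
}

#' Mask sparse matrix columns by the first-mode rule
#'
#' Two steps: zero-sum columns are always masked; then a polynomial (default
#' degree 6) is fitted to the log-density of the non-zero column sums on a
#' 100-bin histogram, and the exclusion threshold is the first local minimum
#' of the fitted curve to the left of its global maximum (the first mode).
#' If no such minimum exists (unimodal sums), only zero columns are masked.
#'
#' @param mat raw \code{\linkS4class{HiCMatrix}}.
#' @param degree polynomial degree for the density fit.
#' @param nBreaks histogram bin count.
#' @return the matrix with its \code{mask} slot set.
#' @export
maskColumns <- function(mat, degree = 6L, nBreaks = 100L) {
  sums <- colSums(mat@counts)
  if (all(sums == 0)) stop("all columns are zero: nothing left to analyse")
  zeroes <- which(sums == 0)
  nz <- sums[sums > 0]
  thr <- 0
  if (length(nz) > degree + 2L && length(unique(nz)) > 2L) {
    h <- hist(nz, breaks = seq(min(nz), max(nz), length.out = nBreaks + 1L),
              plot = FALSE)
    x <- h$mids
    y <- log(h$counts + 1)
    fit <- lm(y ~ poly(x, degree, raw = FALSE))
    yy <- predict(fit)
    gmax <- which.max(yy)
    if (gmax > 2L) {
      d <- diff(yy[1:gmax])
      ## local minima (derivative crosses from <=0 to >0) left of the peak
      mins <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L
      for (mn in mins) {
        ## a genuine valley sits below a preceding mode: require the first
        ## mode and the global mode to be at least 2x denser than the valley
        leftMax <- if (mn > 1L) max(yy[1:(mn - 1L)]) else -Inf
        if (leftMax - yy[mn] >= log(2) && yy[gmax] - yy[mn] >= log(2)) {
          thr <- x[mn]
          break
        }
      }
    }
  }
  mat@mask <- sort(unique(c(zeroes, which(sums > 0 & sums < thr))))
  mat
}

unmaskedIdx <- function(mat) setdiff(seq_len(nrow(mat@counts)), mat@mask)

#' Truncated ICE balancing
#'
#' Iterative correction: at every iteration each unmasked bin's bias is
#' multiplied by its relative row sum (biases recentred to geometric mean 1),
#' and the working matrix is re-divided by the outer product of biases.
#' Iteration stops when the maximum relative deviation of unmasked row sums
#' from their mean is at most \code{maxDev} (default 0.10 -- a deliberately
#' truncated balance), or after \code{maxIter} iterations with a warning.
#' The balanced matrix is rescaled so its total equals the raw total over
#' unmasked bins; the factor is recorded in the returned attributes.
#'
#' @param mat masked \code{\linkS4class{HiCMatrix}}.
#' @param maxDev convergence tolerance on relative row-sum deviation.
#' @param maxIter iteration cap.
#' @return the normalized matrix with \code{biases} filled and
#'   \code{normalized = TRUE}; the achieved deviation and iteration count
#'   are attached to the counts as attributes \code{iceDeviation} and
#'   \code{iceIterations}.
#' @export
iceNormalize <- function(mat, maxDev = 0.10, maxIter = 100L) {
  keep <- unmaskedIdx(mat)
  if (length(keep) < 2L) stop("fewer than two unmasked bins")
  W <- mat@counts[keep, keep, drop = FALSE]
  if (any(rowSums(W) == 0))
    stop("unmasked zero-sum column: run maskColumns() first")
  b <- rep(1, length(keep))
  raw <- W
  iters <- 0L
  repeat {
    s <- rowSums(W)
    m <- mean(s)
    dev <- max(abs(s - m) / m)
    if (dev <= maxDev || iters >= maxIter) break
    db <- s / m
    db <- db / exp(mean(log(db)))     # geometric mean 1 for identifiability
    b <- b * db
    W <- raw / outer(b, b)
    iters <- iters + 1L
  }
  if (dev > maxDev)
    warning(sprintf("ICE stopped at maxIter=%d with deviation %.3g > %.3g",
                    maxIter, dev, maxDev))
  ## preserve total count scale; fold the global factor into the biases
  fac <- sum(raw) / sum(W)
  b <- b / sqrt(fac)
  W <- raw / outer(b, b)
  n <- nrow(mat@counts)
  biases <- rep(NA_real_, n)
  biases[keep] <- b
  cts <- matrix(0, n, n)
  cts[keep, keep] <- W
  out <- mat
  out@counts <- cts
  out@biases <- biases
  out@normalized <- TRUE
  attr(out@counts, "iceDeviation") <- dev
  attr(out@counts, "iceIterations") <- iters
  out
}

#' Maximum relative row-sum deviation over unmasked bins
#'
#' @param mat a \code{\linkS4class{HiCMatrix}}.
#' @return max over unmasked bins of |rowsum - mean| / mean.
#' @export
rowSumDeviation <- function(mat) {
  keep <- unmaskedIdx(mat)
  s <- rowSums(mat@counts[keep, keep, drop = FALSE])
  max(abs(s - mean(s)) / mean(s))
}

#' Merge raw contact matrices
#'
#' Element-wise sum of raw counts of replicate experiments binned on the
#' same genome at the same resolution; masks and biases are recomputed
#' downstream.
#'
#' @param ... two or more raw \code{\linkS4class{HiCMatrix}} objects.
#' @return merged raw matrix.
#' @export
mergeMatrices <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1L)
  ref <- ms[[1L]]
  for (m in ms[-1L]) {
    if (m@resolution != ref@resolution ||
        !identical(m@chromNames, ref@chromNames) ||
        !identical(m@chromLengths, ref@chromLengths))
      stop("matrices are incompatible: different genome or resolution")
    if (m@normalized || ref@normalized)
      stop("merge operates on raw matrices")
    ref@counts <- ref@counts + m@counts
  }
  ref@mask <- integer()
  ref@biases <- numeric()
  ref
}

## ---- text I/O -------------------------------------------------------------

#' Write / read a contact matrix as text
#'
#' Dense format: '#'-prefixed header lines carrying resolution, chromosomes,
#' lengths, mask and biases, followed by the tab-separated matrix.  Triplet
#' format: the same headers followed by \code{bin_i bin_j count} rows for the
#' upper triangle (cooler-style coordinate list); both round-trip to
#' identical objects.
#'
#' @param mat a \code{\linkS4class{HiCMatrix}}.
#' @param path output file.
#' @param format \code{"dense"} or \code{"triplet"}.
#' @export
writeHiCMatrix <- function(mat, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# resolution\t%g", mat@resolution),
    sprintf("# chromosomes\t%s", paste(mat@chromNames, collapse = ",")),
    sprintf("# lengths\t%s", paste(mat@chromLengths, collapse = ",")),
    sprintf("# mask\t%s", paste(mat@mask, collapse = ",")),
    sprintf("# biases\t%s", paste(signif(mat@biases, 12), collapse = ",")),
    sprintf("# normalized\t%d", as.integer(mat@normalized)),
    sprintf("# format\t%s", format)), con)
  if (format == "dense") {
    write.table(mat@counts, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(mat@counts, diag = TRUE) & mat@counts != 0,
                 arr.ind = TRUE)
    write.table(data.frame(idx[, 1L], idx[, 2L],
                           mat@counts[idx]), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeHiCMatrix
#' @export
readHiCMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(key) sub(sprintf("^# %s\t", key), "",
                            grep(sprintf("^# %s\t", key), hdr, value = TRUE)[1L])
  res <- as.numeric(getf("resolution"))
  chroms <- strsplit(getf("chromosomes"), ",")[[1L]]
  lens <- as.numeric(strsplit(getf("lengths"), ",")[[1L]])
  mat <- emptyHiCMatrix(setNames(lens, chroms), res)
  maskStr <- getf("mask")
  if (nzchar(maskStr)) mat@mask <- as.integer(strsplit(maskStr, ",")[[1L]])
  biasStr <- getf("biases")
  if (nzchar(biasStr)) mat@biases <- as.numeric(strsplit(biasStr, ",")[[1L]])
  mat@normalized <- getf("normalized") == "1"
  fmt <- getf("format")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  n <- nrow(mat@counts)
  if (fmt == "dense") {
    cts <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    if (nrow(cts) != n) stop("dense matrix body does not match genome tiling")
    mat@counts <- unname(cts)
  } else {
    if (length(body)) {
      tri <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
      cts <- matrix(0, n, n)
      cts[cbind(tri[, 1L], tri[, 2L])] <- tri[, 3L]
      cts[cbind(tri[, 2L], tri[, 1L])] <- tri[, 3L]
      mat@counts <- cts
    }
  }
  validObject(mat)
  mat
}

#' Extract one chromosome's submatrix
#'
#' @param mat genome-wide \code{\linkS4class{HiCMatrix}}.
#' @param chrom chromosome name.
#' @return single-chromosome \code{\linkS4class{HiCMatrix}} with mask and
#'   biases subset accordingly.
#' @export
chromosomeSubmatrix <- function(mat, chrom) {
  rng <- chromBinRange(mat, chrom)
  idx <- seq(rng[1L], rng[2L])
  k <- match(chrom, mat@chromNames)
  out <- new("HiCMatrix", counts = mat@counts[idx, idx, drop = FALSE],
             resolution = mat@resolution, chromNames = chrom,
             chromLengths = mat@chromLengths[k],
             offsets = setNames(0, chrom),
             mask = as.integer(intersect(mat@mask, idx) - rng[1L] + 1L),
             biases = if (length(mat@biases)) mat@biases[idx] else numeric(),
             normalized = mat@normalized)
  validObject(out)
  out
}
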