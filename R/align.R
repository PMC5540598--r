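## Alignment of TAD-border lists across experiments: global
## Needleman-Wunsch on border positions (bp) or reciprocal-closest matching,
## plus agreement percentages at a distance tolerance.

#' Needleman-Wunsch alignment of two border lists
#'
#' Global alignment of two ascending border-position lists (bp) maximizing
#' the summed match scores minus gap penalties, with match score
#' \code{max(0, 1 - |a - b| / maxDist)}.  Positions are compared in bp so
#' lists from different resolutions align.
#'
#' @param bordersA,bordersB numeric border positions in bp (sorted; unsorted
#'   input is sorted with a warning).
#' @param maxDist distance (bp) at which the match score reaches 0.
#' @param gapPenalty cost of leaving a border unmatched.
#' @return list with \code{score}, \code{matches} (data.frame \code{a, b,
#'   distance} of matched positions) and \code{columns} (data.frame
#'   \code{a, b} with \code{NA} for gaps, in alignment order).
#' @export
alignBordersNW <- function(bordersA, bordersB, maxDist = 1e5,
                           gapPenalty = 0.2) {
  if (is.unsorted(bordersA)) { warning("bordersA unsorted; sorting"); bordersA <- sort(bordersA) }
  if (is.unsorted(bordersB)) { warning("bordersB unsorted; sorting"); bordersB <- sort(bordersB) }
  na <- length(bordersA); nb <- length(bordersB)
  sc <- function(a, b) max(0, 1 - abs(a - b) / maxDist)
  F <- matrix(0, na + 1L, nb + 1L)
  F[, 1L] <- -gapPenalty * (0:na)
  F[1L, ] <- -gapPenalty * (0:nb)
  ptr <- matrix(0L, na + 1L, nb + 1L)   # 1 diag, 2 up (gap in B), 3 left
  ptr[, 1L] <- 2L; ptr[1L, ] <- 3L; ptr[1L, 1L] <- 0L
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cand <- c(F[i, j] + sc(bordersA[i], bordersB[j]),
              F[i, j + 1L] - gapPenalty,
              F[i + 1L, j] - gapPenalty)
    k <- which.max(cand)
    F[i + 1L, j + 1L] <- cand[k]
    ptr[i + 1L, j + 1L] <- k
  }
  ## traceback
  i <- na; j <- nb
  colsA <- colsB <- numeric(0)
  while (i > 0L || j > 0L) {
    k <- ptr[i + 1L, j + 1L]
    if (k == 1L) { colsA <- c(bordersA[i], colsA); colsB <- c(bordersB[j], colsB); i <- i - 1L; j <- j - 1L }
    else if (k == 2L) { colsA <- c(bordersA[i], colsA); colsB <- c(NA, colsB); i <- i - 1L }
    else { colsA <- c(NA, colsA); colsB <- c(bordersB[j], colsB); j <- j - 1L }
  }
  m <- !is.na(colsA) & !is.na(colsB)
  list(score = F[na + 1L, nb + 1L],
       matches = data.frame(a = colsA[m], b = colsB[m],
                            distance = abs(colsA[m] - colsB[m])),
       columns = data.frame(a = colsA, b = colsB))
}

#' Reciprocal-closest matching of two border lists
#'
#' (a, b) are matched iff b is a's nearest neighbour, a is b's nearest
#' neighbour, and \code{|a - b| <= maxDist}.  Nearest-neighbour ties are
#' broken to the leftmost candidate.
#'
#' @inheritParams alignBordersNW
#' @return data.frame \code{a, b, distance} of matched positions.
#' @export
alignReciprocal <- function(bordersA, bordersB, maxDist = 1e5) {
  if (length(bordersA) == 0L || length(bordersB) == 0L)
    return(data.frame(a = numeric(), b = numeric(), distance = numeric()))
  bordersA <- sort(bordersA); bordersB <- sort(bordersB)
  nn <- function(x, ref) vapply(x, function(p) which.min(abs(ref - p)), 1L)
  aToB <- nn(bordersA, bordersB)
  bToA <- nn(bordersB, bordersA)
  ia <- which(bToA[aToB] == seq_along(bordersA) &
              abs(bordersA - bordersB[aToB]) <= maxDist)
  data.frame(a = bordersA[ia], b = bordersB[aToB[ia]],
             distance = abs(bordersA[ia] - bordersB[aToB[ia]]))
}

#' Border agreement percentage
#'
#' Percentage of reference borders having an aligned partner within
#' \code{tolerance} bp.  Agreement is asymmetric when list sizes differ:
#' swap \code{reference} to see both directions.
#'
#' @param alignment result of \code{\link{alignBordersNW}} or a matches
#'   data.frame from \code{\link{alignReciprocal}}.
#' @param tolerance distance tolerance in bp.
#' @param reference \code{"a"} or \code{"b"}: whose borders are the
#'   denominator.
#' @param nA,nB reference list sizes; taken from alignment \code{columns}
#'   when available.
#' @return percentage in [0, 100].
#' @export
borderAgreement <- function(alignment, tolerance, reference = c("a", "b"),
                            nA = NULL, nB = NULL) {
  reference <- match.arg(reference)
  matches <- if (is.data.frame(alignment)) alignment else alignment$matches
  if (is.null(nA) || is.null(nB)) {
    if (is.data.frame(alignment))
      stop("supply nA and nB for reciprocal matches")
    nA <- sum(!is.na(alignment$columns$a))
    nB <- sum(!is.na(alignment$columns$b))
  }
  denom <- if (reference == "a") nA else nB
  if (denom == 0L) stop("empty reference border list")
  100 * sum(matches$distance <= tolerance) / denom
}

#' Progressive multi-experiment border alignment
#'
#' Aligns more than two border lists by progressive Needleman-Wunsch against
#' a growing consensus: lists are taken in descending size order, each is
#' aligned to the consensus, matched consensus positions are updated to the
#' running mean, and unmatched borders extend the consensus.
#'
#' @param borderLists named list of numeric position vectors (bp).
#' @param maxDist,gapPenalty passed to \code{\link{alignBordersNW}}.
#' @return list with \code{consensus} positions and \code{table}, a matrix
#'   (experiments x consensus columns) of aligned positions (NA = gap).
#' @export
alignMultiple <- function(borderLists, maxDist = 1e5, gapPenalty = 0.2) {
  stopifnot(length(borderLists) >= 2L)
  ord <- order(vapply(borderLists, length, 1L), decreasing = TRUE)
  lists <- borderLists[ord]
  consensus <- sort(lists[[1L]])
  rows <- list()
  rows[[names(lists)[1L]]] <- consensus
  for (k in 2:length(lists)) {
    al <- alignBordersNW(consensus, sort(lists[[k]]), maxDist, gapPenalty)
    newCons <- ifelse(is.na(al$columns$a), al$columns$b,
                      ifelse(is.na(al$columns$b), al$columns$a,
                             (al$columns$a + al$columns$b) / 2))
    ## re-express previous rows on the new consensus columns
    mapOld <- match(al$columns$a, consensus)
    rows <- lapply(rows, function(r) {
      out <- rep(NA_real_, length(newCons))
      out[!is.na(mapOld)] <- r[mapOld[!is.na(mapOld)]]
      out
    })
    rows[[names(lists)[k]]] <- al$columns$b
    consensus <- newCons
    o <- order(consensus)
    consensus <- consensus[o]
    rows <- lapply(rows, function(r) r[o])
  }
  tab <- do.call(rbind, rows)[names(borderLists), , drop = FALSE]
  list(consensus = consensus, table = tab)
}
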