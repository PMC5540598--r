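#' @import methods
#' @importFrom stats cor quantile median aov TukeyHSD sd runif rnorm rpois
#'   setNames complete.cases optim lm poly predict dist
#' @importFrom graphics hist
#' @importFrom utils read.table write.table head tail
#' @useDynLib tadmod, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Restriction-fragment map of a genome
#'
#' Holds, per chromosome, the sorted restriction cut sites (0-based bp, the
#' position of the cut within the recognition motif) produced by in-silico
#' digestion.  Fragments are the half-open intervals \code{[start, end)}
#' between consecutive cuts; they tile each chromosome exactly.  Fragment ids
#' are 1-based per chromosome.
#'
#' @slot motif recognition motif (ACGT string, e.g. \code{"AAGCTT"} for
#'   HindIII).
#' @slot cutOffset 0-based offset of the cut within the motif (HindIII cuts
#'   after 1 nt).
#' @slot cuts named list; per chromosome an increasing numeric vector of
#'   0-based cut positions (may be empty).
#' @slot seqlengths named numeric vector of chromosome lengths in bp; the
#'   name order is the genome order and defines genome-wide bin offsets
#'   downstream.
#' @export
setClass("FragmentMap",
  representation(motif = "character", cutOffset = "integer",
                 cuts = "list", seqlengths = "numeric"))

setValidity("FragmentMap", function(object) {
  msg <- NULL
  if (length(object@seqlengths) == 0L)
    msg <- c(msg, "empty genome: no chromosomes")
  if (is.null(names(object@seqlengths)) ||
      anyDuplicated(names(object@seqlengths)))
    msg <- c(msg, "chromosome names must be unique and non-empty")
  if (!setequal(names(object@cuts), names(object@seqlengths)))
    msg <- c(msg, "cuts and seqlengths must cover the same chromosomes")
  for (chr in names(object@cuts)) {
    cc <- object@cuts[[chr]]
    if (length(cc) && (is.unsorted(cc, strictly = TRUE) ||
        cc[1L] < 0 || cc[length(cc)] > object@seqlengths[[chr]]))
      msg <- c(msg, sprintf("cut sites of %s not strictly increasing in range", chr))
  }
  if (is.null(msg)) TRUE else msg
})

#' Binned Hi-C contact matrix
#'
#' Symmetric genome-wide (or region) contact matrix at a fixed resolution.
#' Bins are 1-based, ordered chromosome by chromosome; the last bin of a
#' chromosome may cover fewer than \code{resolution} bp but is a full bin
#' index.  \code{mask} holds bin indices excluded from all downstream
#' statistics; \code{biases} are per-bin multiplicative ICE biases (length 0
#' until normalization).
#'
#' @slot counts symmetric numeric matrix of contact counts (raw) or balanced
#'   values (after \code{\link{iceNormalize}}).
#' @slot resolution bin size in bp.
#' @slot chromNames,chromLengths genome order and lengths (bp).
#' @slot offsets named numeric; number of bins preceding each chromosome.
#' @slot mask integer vector of masked bin indices (1-based, sorted).
#' @slot biases numeric per-bin biases, or length 0.
#' @slot normalized logical flag.
#' @export
setClass("HiCMatrix",
  representation(counts = "matrix", resolution = "numeric",
                 chromNames = "character", chromLengths = "numeric",
                 offsets = "numeric", mask = "integer",
                 biases = "numeric", normalized = "logical"))

setValidity("HiCMatrix", function(object) {
  msg <- NULL
  n <- nrow(object@counts)
  if (n != ncol(object@counts)) msg <- c(msg, "counts must be square")
  nb <- sum(ceiling(object@chromLengths / object@resolution))
  if (n != nb)
    msg <- c(msg, sprintf("matrix has %d bins but genome tiling needs %d", n, nb))
  if (length(object@mask) && (min(object@mask) < 1L || max(object@mask) > n))
    msg <- c(msg, "mask indices out of range")
  if (length(object@biases) && length(object@biases) != n)
    msg <- c(msg, "biases must have one entry per bin")
  if (n > 0 && max(abs(object@counts - t(object@counts))) > 1e-8 * (1 + max(abs(object@counts))))
    msg <- c(msg, "counts must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' TAD segmentation of a chromosome
#'
#' Result of the dynamic-programming change-point segmentation.  Borders are
#' the 1-based start bins of each TAD in ascending order (the first is always
#' bin 1), so \code{m = length(borders)} TADs tile the chromosome.  Each
#' border carries a robustness score 1-10: the number of constrained-optimal
#' segmentations with m*, m*+1, ..., m*+9 domains that retain the border at
#' the same bin.
#'
#' @slot borders integer start bins (ascending, first = 1).
#' @slot strengths integer 1-10 per border.
#' @slot densityRatio per-TAD mean observed/expected intra-TAD ratio.
#' @slot densityFlag per-TAD \code{"higher"}/\code{"lower"} than expected.
#' @slot logLik total penalized log-likelihood at the optimum.
#' @slot nBins number of bins segmented.
#' @slot resolution bp per bin.
#' @slot chrom chromosome name.
#' @export
setClass("TadSegmentation",
  representation(borders = "integer", strengths = "integer",
                 densityRatio = "numeric", densityFlag = "character",
                 logLik = "numeric", nBins = "integer",
                 resolution = "numeric", chrom = "character"))

setValidity("TadSegmentation", function(object) {
  msg <- NULL
  b <- object@borders
  if (length(b) == 0L || b[1L] != 1L) msg <- c(msg, "first TAD must start at bin 1")
  if (is.unsorted(b, strictly = TRUE)) msg <- c(msg, "borders must be strictly increasing")
  if (length(object@strengths) != length(b))
    msg <- c(msg, "one strength per border required")
  if (length(object@strengths) &&
      (min(object@strengths) < 1L || max(object@strengths) > 10L))
    msg <- c(msg, "strengths must lie in [1,10]")
  if (is.null(msg)) TRUE else msg
})

#' Set of spatial restraints for one modelled region
#'
#' Typed distance restraints between particles of a homopolymer chain, as
#' derived from z-scored contact frequencies: \code{harmonic} (two-sided),
#' \code{lower} (harmonic lower bound, penalised only when closer than the
#' equilibrium distance) and \code{upper} (penalised only when farther).
#'
#' @slot i,j 1-based particle indices, \code{i < j}, no duplicates.
#' @slot kind one of \code{"harmonic"}, \code{"lower"}, \code{"upper"} per
#'   restraint.
#' @slot dist equilibrium distance (nm).
#' @slot k force constant (per nm^2).
#' @slot radius particle radius (nm).
#' @slot nParticles chain length.
#' @export
setClass("RestraintSet",
  representation(i = "integer", j = "integer", kind = "character",
                 dist = "numeric", k = "numeric",
                 radius = "numeric", nParticles = "integer"))

setValidity("RestraintSet", function(object) {
  msg <- NULL
  if (any(object@i >= object@j)) msg <- c(msg, "restraints must have i < j")
  if (anyDuplicated(cbind(object@i, object@j)))
    msg <- c(msg, "duplicate (i,j) restraint")
  if (!all(object@kind %in% c("harmonic", "lower", "upper")))
    msg <- c(msg, "unknown restraint kind")
  n <- object@nParticles
  if (n >= 2L) {
    cons <- object@i + 1L == object@j
    have <- object@i[cons]
    if (!all(seq_len(n - 1L) %in% have))
      msg <- c(msg, "consecutive particles must always be restrained")
  }
  if (any(object@dist < 0) || any(object@k < 0))
    msg <- c(msg, "distances and force constants must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Ensemble of 3D models of one genomic region
#'
#' @slot coords list of n x 3 coordinate matrices (nm), sorted by objective
#'   ascending.
#' @slot objectives objective value per model.
#' @slot seeds RNG seed per model.
#' @slot region named list: chrom, start, end, resolution.
#' @slot params the \code{ModelingParams} list used.
#' @export
setClass("ModelEnsemble",
  representation(coords = "list", objectives = "numeric",
                 seeds = "integer", region = "list", params = "list"))

setValidity("ModelEnsemble", function(object) {
  msg <- NULL
  if (length(object@coords) != length(object@objectives))
    msg <- c(msg, "one objective per model required")
  ns <- vapply(object@coords, nrow, 1L)
  if (length(ns) && length(unique(ns)) != 1L)
    msg <- c(msg, "all models must have the same particle count")
  if (any(!vapply(object@coords, function(x) all(is.finite(x)), TRUE)))
    msg <- c(msg, "coordinates must be finite")
  if (is.unsorted(object@objectives))
    msg <- c(msg, "models must be sorted by objective ascending")
  if (is.null(msg)) TRUE else msg
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "FragmentMap", function(object) {
  nf <- sum(vapply(object@cuts, length, 1L)) + length(object@seqlengths)
  cat(sprintf("FragmentMap: %d chromosomes, %d fragments (motif %s, cut %d)\n",
              length(object@seqlengths), nf, object@motif, object@cutOffset))
})

setMethod("show", "HiCMatrix", function(object) {
  cat(sprintf(
    "HiCMatrix: %d bins @ %g bp, %d chromosome(s), %d masked, %s\n",
    nrow(object@counts), object@resolution, length(object@chromNames),
    length(object@mask),
    if (object@normalized) "ICE-normalized" else "raw"))
})

setMethod("show", "TadSegmentation", function(object) {
  cat(sprintf("TadSegmentation: %d TADs over %d bins of %s (penalized logLik %.2f)\n",
              length(object@borders), object@nBins, object@chrom, object@logLik))
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet: %d particles, %d restraints (%s)\n",
              object@nParticles, length(object@i),
              paste(sprintf("%s: %d", names(table(object@kind)),
                            as.integer(table(object@kind))), collapse = ", ")))
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d models x %d particles, objectives [%.3g, %.3g]\n",
              length(object@coords),
              if (length(object@coords)) nrow(object@coords[[1L]]) else 0L,
              min(object@objectives), max(object@objectives)))
})

## ---- accessors ------------------------------------------------------------

#' Accessors for tadmod S4 objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x a tadmod S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
contactCounts <- function(x) x@counts

#' @rdname accessors
#' @export
binResolution <- function(x) x@resolution

#' @rdname accessors
#' @export
maskedBins <- function(x) x@mask

#' @rdname accessors
#' @export
binBiases <- function(x) x@biases

#' @rdname accessors
#' @export
tadBorders <- function(x) x@borders

#' @rdname accessors
#' @export
borderStrengths <- function(x) x@strengths

#' @rdname accessors
#' @export
modelCoords <- function(x) x@coords

#' @rdname accessors
#' @export
modelObjectives <- function(x) x@objectives
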