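# Shared fixtures, all built in code at test time.

# tiny deterministic genome with known HindIII cut layout
tinyGenome <- function() c(chrA = "TTAAGCTTGG", chrB = "AAGCTTAAGCTT")

# independent string-scan digestion oracle (0-based cut positions)
scanCuts <- function(seq, motif, cutOffset) {
  hits <- integer(0)
  L <- nchar(motif)
  for (p in seq_len(nchar(seq) - L + 1L))
    if (substr(seq, p, p + L - 1L) == motif) hits <- c(hits, p - 1L + cutOffset)
  hits[hits > 0 & hits < nchar(seq)]
}

# independent linear-scan fragment locator
scanLocate <- function(cuts, len, pos) {
  bounds <- c(0, cuts, len)
  for (f in seq_len(length(bounds) - 1L))
    if (pos >= bounds[f] && pos < bounds[f + 1L])
      return(list(fragment = f, up = pos - bounds[f],
                  down = bounds[f + 1L] - pos))
  stop("position outside chromosome")
}

# write a FASTQ with uniform quality 'I' (PHRED 40 at offset 33)
writeTestFastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0("@read", i), seqs[[i]], "+",
      strrep("I", nchar(seqs[[i]]))))), path)
  path
}

# motif-free filler of fixed length (deterministic)
noMotif <- function(len) strrep("ACGT", ceiling(len / 4)) |> substr(1, len)

# wrap a plain symmetric matrix into a single-chromosome HiCMatrix
asHiC <- function(counts, resolution = 1e4, chrom = "chrA") {
  h <- emptyHiCMatrix(setNames(nrow(counts) * resolution, chrom), resolution)
  h@counts <- unname(counts)
  h
}

# exhaustive best segmentation for small n: enumerate all internal border
# sets honouring the length constraints; returns best penalized score and
# borders, scoring segments with segmentScore() on a fixed expectation
bruteSegment <- function(counts, minTad = 2L, maxTad = nrow(counts)) {
  n <- nrow(counts)
  E <- decayExpectation(counts)
  Tcells <- sum(!is.na(E[upper.tri(E, diag = TRUE)]))
  best <- list(score = -Inf, borders = NULL)
  cand <- 2:n
  for (mask in 0:(2^length(cand) - 1L)) {
    borders <- c(1L, cand[bitwAnd(bitwShiftR(mask, seq_along(cand) - 1L), 1L) == 1L])
    lens <- diff(c(borders, n + 1L))
    if (any(lens < minTad) || any(lens > maxTad)) next
    sc <- sum(mapply(function(i, j) segmentScore(counts, E, i, j),
                     borders, c(borders[-1L] - 1L, n)))
    m <- length(borders)
    sc <- sc - (2 * m - 1) / 2 * log(max(Tcells, 2L))
    if (sc > best$score) best <- list(score = sc, borders = borders)
  }
  best
}

# brute-force optimal Needleman-Wunsch alignment score by enumeration of
# all monotone matchings (lists <= 6)
bruteAlignScore <- function(a, b, maxDist, gap) {
  sc <- function(x, y) max(0, 1 - abs(x - y) / maxDist)
  rec <- function(i, j) {
    if (i > length(a) && j > length(b)) return(0)
    if (i > length(a)) return(-gap * (length(b) - j + 1L))
    if (j > length(b)) return(-gap * (length(a) - i + 1L))
    max(rec(i + 1L, j + 1L) + sc(a[i], b[j]),
        rec(i + 1L, j) - gap,
        rec(i, j + 1L) - gap)
  }
  rec(1L, 1L)
}
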