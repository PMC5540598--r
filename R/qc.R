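## Hi-C-aware FASTQ quality control: per-cycle PHRED profile plus digestion
## statistics (undigested motifs, strict dangling ends, re-ligation
## junctions).

#' Re-ligation junction sequence of a restriction enzyme
#'
#' A Hi-C ligation event joins two filled-in cut ends, so the junction reads
#' \code{motif[1..L-cut] + motif[cut+1..L]} (1-based substrings; \code{L} =
#' motif length).  For HindIII (\code{AAGCTT}, cut after 1 nt) this is
#' \code{AAGCTAGCTT}, of length \code{2L - 2*min(cut, L - cut)} for a
#' palindromic motif.
#'
#' @param motif recognition sequence.
#' @param cutOffset 0-based cut position within the motif.
#' @return junction string.
#' @export
ligationJunction <- function(motif, cutOffset) {
  motif <- toupper(motif)
  L <- nchar(motif)
  cutOffset <- as.integer(cutOffset)
  stopifnot(cutOffset >= 0L, cutOffset < L)
  paste0(substr(motif, 1L, L - cutOffset), substr(motif, cutOffset + 1L, L))
}

## remainder left on a fragment 5' end after digestion (strict dangling-end
## prefix): for HindIII, "AGCTT"
.danglingPrefix <- function(motif, cutOffset) {
  substr(toupper(motif), cutOffset + 1L, nchar(motif))
}

.readFastq <- function(path, n) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    nrec = as.integer(n), with.qualities = TRUE)
  if (length(x) == 0L) stop("no reads in ", path)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

## vectorised per-cycle occurrence counting of a fixed pattern
.perCycleCounts <- function(seqs, pattern, readLen) {
  counts <- integer(readLen)
  hits <- gregexpr(pattern, seqs, fixed = TRUE)
  for (h in hits) {
    if (h[1L] != -1L) counts[h] <- counts[h] + 1L
  }
  counts
}

#' FASTQ quality profile
#'
#' Mean PHRED score and N count per sequencing cycle over the first
#' \code{nReads} reads.  Reads longer than the shortest read are truncated to
#' the common length for the per-cycle profile.
#'
#' @param path FASTQ file (plain or gzip; auto-detected).
#' @param nReads number of reads to examine (default 1e6, the usual
#'   first-million spot check).
#' @param phredOffset 33 (Sanger/Illumina 1.8+) or 64.
#' @return list with \code{meanPhred}, \code{nCount} (per cycle),
#'   \code{readLength}, \code{nExamined}.
#' @export
qualityProfile <- function(path, nReads = 1e6, phredOffset = 33L) {
  if (!phredOffset %in% c(33L, 64L)) stop("phredOffset must be 33 or 64")
  fq <- .readFastq(path, nReads)
  readLen <- min(nchar(fq$seq))
  qm <- vapply(fq$qual, function(q)
    utf8ToInt(substr(q, 1L, readLen)) - phredOffset, numeric(readLen),
    USE.NAMES = FALSE)
  qm <- matrix(qm, nrow = readLen)
  sm <- vapply(fq$seq, function(s)
    utf8ToInt(substr(s, 1L, readLen)), numeric(readLen), USE.NAMES = FALSE)
  sm <- matrix(sm, nrow = readLen)
  list(meanPhred = rowMeans(qm),
       nCount = as.integer(rowSums(sm == utf8ToInt("N"))),
       readLength = readLen,
       nExamined = length(fq$seq))
}

#' Hi-C digestion statistics of a FASTQ file
#'
#' Counts, per sequencing cycle, (i) complete undigested occurrences of the
#' restriction motif, (ii) strict dangling-end starts (reads beginning with
#' the post-cut motif remainder) and (iii) re-ligation junction occurrences,
#' over the first \code{nReads} reads.  A read counts as digested when it
#' contains no complete undigested motif; a ligated read carries the junction
#' sequence, not the intact motif, so motif fragments truncated at the read
#' ends never count.
#'
#' @inheritParams qualityProfile
#' @param motif restriction motif (e.g. \code{"AAGCTT"}).
#' @param cutOffset 0-based cut position within the motif.
#' @return list with per-cycle integer vectors \code{undigested},
#'   \code{danglingStarts}, \code{junction}, and summary percentages
#'   \code{digestedPct}, \code{danglingPct}, plus \code{nExamined},
#'   \code{readLength}.
#' @export
ligationStats <- function(path, motif, cutOffset, nReads = 1e6) {
  fq <- .readFastq(path, nReads)
  readLen <- min(nchar(fq$seq))
  seqs <- substr(fq$seq, 1L, readLen)
  n <- length(seqs)
  motif <- toupper(motif)
  junction <- ligationJunction(motif, cutOffset)
  dangle <- .danglingPrefix(motif, cutOffset)

  undig <- .perCycleCounts(seqs, motif, readLen)
  junc <- .perCycleCounts(seqs, junction, readLen)
  readsWithMotif <- sum(grepl(motif, seqs, fixed = TRUE))
  dangling <- startsWith(seqs, dangle)
  danglingStarts <- integer(readLen)
  danglingStarts[1L] <- sum(dangling)

  list(undigested = undig,
       danglingStarts = danglingStarts,
       junction = junc,
       digestedPct = 100 - 100 * readsWithMotif / n,
       danglingPct = 100 * sum(dangling) / n,
       readLength = readLen,
       nExamined = n)
}

#' Write a QC report to JSON
#'
#' @param report list from \code{\link{qualityProfile}} and/or
#'   \code{\link{ligationStats}} (lists are concatenated).
#' @param path output JSON file.
#' @export
writeQcReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
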