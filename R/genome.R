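## Restriction-fragment map construction and queries.
## Coordinates are 0-based half-open throughout; cut sites are the 0-based
## position of the scission within each motif occurrence.

#' Read a genome from a (multi-)FASTA file
#'
#' Wraps \code{Biostrings::readDNAStringSet}; sequences are uppercased and
#' the name of each record is truncated at the first whitespace, matching the
#' usual chromosome naming of reference FASTA files.
#'
#' @param path FASTA file (plain or gzip).
#' @return a \code{DNAStringSet} whose names are chromosome names, in file
#'   order (the genome order used for bin offsets downstream).
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate chromosome names in ", path)
  g
}

genomeLengths <- function(genome) {
  if (is.character(genome) && all(nchar(genome) > 0) && !is.null(names(genome)))
    return(setNames(nchar(genome), names(genome)))
  setNames(as.numeric(Biostrings::width(genome)), names(genome))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

.motifHits <- function(seqstr, motif) {
  ## 0-based start positions of motif occurrences in a character sequence
  v <- Biostrings::matchPattern(motif, Biostrings::DNAString(seqstr))
  Biostrings::start(v) - 1L
}

#' Digest a genome in silico
#'
#' Scans every chromosome for the restriction motif and records the cut site
#' of each occurrence (occurrence start + \code{cutOffset}, 0-based).
#' Palindromic motifs (e.g. HindIII \code{AAGCTT}) are searched on the
#' forward strand only; non-palindromic motifs are additionally searched as
#' their reverse complement with the cut mapped back to forward coordinates.
#' Chromosomes without any occurrence become a single whole-chromosome
#' fragment.
#'
#' @param genome a \code{DNAStringSet} (see \code{\link{readGenome}}) or a
#'   named character vector of sequences.
#' @param motif recognition sequence, ACGT only.
#' @param cutOffset 0-based cut position within the motif (HindIII: 1).
#' @return a \code{\linkS4class{FragmentMap}}.
#' @examples
#' fm <- digestGenome(c(chrA = "TTAAGCTTGG"), "AAGCTT", 1)
#' fragmentTable(fm)   # fragments [0,3) and [3,10)
#' @export
digestGenome <- function(genome, motif, cutOffset = 1L) {
  motif <- toupper(motif)
  if (nchar(motif) == 0L || grepl("[^ACGT]", motif))
    stop("invalid motif: must be a non-empty ACGT-only string")
  cutOffset <- as.integer(cutOffset)
  if (cutOffset < 0L || cutOffset >= nchar(motif))
    stop("cutOffset must satisfy 0 <= cutOffset < motif length")
  lens <- genomeLengths(genome)
  if (length(lens) == 0L) stop("empty genome: no chromosomes")
  seqs <- if (is.character(genome)) toupper(genome) else
    setNames(as.character(genome), names(genome))
  rc <- .revcomp(motif)
  L <- nchar(motif)
  cuts <- lapply(names(lens), function(chr) {
    s <- seqs[[chr]]
    cc <- .motifHits(s, motif) + cutOffset
    if (rc != motif) {
      ## minus-strand occurrence starting at p cuts at p + (L - cutOffset)
      cc <- c(cc, .motifHits(s, rc) + (L - cutOffset))
    }
    cc <- sort(unique(as.numeric(cc)))
    ## cuts at 0 or chromosome end do not split anything
    cc[cc > 0 & cc < lens[[chr]]]
  })
  names(cuts) <- names(lens)
  new("FragmentMap", motif = motif, cutOffset = cutOffset,
      cuts = cuts, seqlengths = lens)
}

fragmentBounds <- function(fragmap, chrom) {
  cc <- fragmap@cuts[[chrom]]
  if (is.null(cc)) stop("unknown chromosome: ", chrom)
  len <- fragmap@seqlengths[[chrom]]
  list(start = c(0, cc), end = c(cc, len))
}

#' Locate the fragment containing a position
#'
#' Binary search for the unique fragment tile containing \code{pos}
#' (0-based), returning the 1-based fragment id and the distances to the
#' upstream and downstream cut (fragment boundaries).
#'
#' @param fragmap a \code{\linkS4class{FragmentMap}}.
#' @param chrom chromosome name.
#' @param pos 0-based position(s); vectorised.
#' @return data.frame with columns \code{fragment}, \code{upstream},
#'   \code{downstream}.
#' @export
locateFragment <- function(fragmap, chrom, pos) {
  b <- fragmentBounds(fragmap, chrom)
  len <- fragmap@seqlengths[[chrom]]
  if (any(pos < 0 | pos >= len))
    stop(sprintf("position out of range [0, %d) on %s", len, chrom))
  ## fragment id = 1 + number of cuts <= pos
  id <- findInterval(pos, b$start)
  data.frame(fragment = as.integer(id),
             upstream = pos - b$start[id],
             downstream = b$end[id] - pos)
}

#' Fragment table of a FragmentMap
#'
#' @param fragmap a \code{\linkS4class{FragmentMap}}.
#' @return data.frame \code{chrom, start, end, fragment_id} (0-based
#'   half-open, BED-compatible).
#' @export
fragmentTable <- function(fragmap) {
  do.call(rbind, lapply(names(fragmap@seqlengths), function(chr) {
    b <- fragmentBounds(fragmap, chr)
    data.frame(chrom = chr, start = b$start, end = b$end,
               fragment_id = seq_along(b$start))
  }))
}

#' Write / read a FragmentMap as BED
#'
#' Plain BED4: \code{chrom start end fragment_id}, 0-based half-open.  On
#' read, the motif and cut offset must be supplied (BED does not carry them).
#'
#' @param fragmap a \code{\linkS4class{FragmentMap}}.
#' @param path output/input file.
#' @export
writeFragmentBed <- function(fragmap, path) {
  write.table(fragmentTable(fragmap), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentBed
#' @param motif,cutOffset enzyme description to store on the rebuilt map.
#' @export
readFragmentBed <- function(path, motif = "N", cutOffset = 0L) {
  bed <- read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "fragment_id"),
                    colClasses = c("character", "numeric", "numeric", "integer"))
  chroms <- unique(bed$chrom)
  lens <- vapply(chroms, function(ch) max(bed$end[bed$chrom == ch]), 0)
  cuts <- lapply(chroms, function(ch) {
    st <- sort(bed$start[bed$chrom == ch])
    st[st > 0]
  })
  names(cuts) <- chroms
  new("FragmentMap", motif = toupper(motif), cutOffset = as.integer(cutOffset),
      cuts = cuts, seqlengths = setNames(lens, chroms))
}
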