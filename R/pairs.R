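## Classification of mapped Hi-C read pairs by the ten ligation-artifact
## criteria, and the accounting report.  Pairs are plain data.frames in the
## tab-separated pairs-like dialect:
##   read_id chrom1 pos1 strand1 chrom2 pos2 strand2 [frag1 frag2]
## positions are 0-based bp of the 5' mapped base.

PAIR_FILTERS <- c("self_circle", "dangling_end", "error", "extra_dangling",
                  "too_close_re", "too_short", "too_large",
                  "over_represented", "duplicated", "random_break")

#' Default read-pair filter parameters
#'
#' Thresholds of the fragment-based artifact filters.  All are protocol
#' parameters, not universal constants, and every one can be overridden.
#'
#' @param maxMoleculeLength maximum sequenced molecule length (bp); bounds
#'   both the extra dangling-end separation and the random-break ligation
#'   distance sum.
#' @param minDistToRe minimum distance (bp) from a read 5' end to the nearest
#'   restriction cut site.
#' @param minFragSize,maxFragSize acceptable restriction-fragment lengths (bp).
#' @param overRepFraction fraction of most pair-dense fragments to blacklist.
#' @return named list of parameters.
#' @export
filterParams <- function(maxMoleculeLength = 500, minDistToRe = 5,
                         minFragSize = 50, maxFragSize = 1e5,
                         overRepFraction = 0.005) {
  if (overRepFraction <= 0 || overRepFraction >= 1)
    stop("overRepFraction must lie in (0, 1)")
  list(maxMoleculeLength = maxMoleculeLength, minDistToRe = minDistToRe,
       minFragSize = minFragSize, maxFragSize = maxFragSize,
       overRepFraction = overRepFraction)
}

#' Read / write mapped pairs
#'
#' Tab-separated pairs records with '#' comment lines; gzip handled
#' transparently.
#'
#' @param path pairs file.
#' @return data.frame with columns \code{read_id, chrom1, pos1, strand1,
#'   chrom2, pos2, strand2} (and \code{frag1, frag2} if present).
#' @export
readPairsFile <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  base <- c("read_id", "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  if (ncol(df) == 7L) names(df) <- base
  else if (ncol(df) == 9L) names(df) <- c(base, "frag1", "frag2")
  else stop("pairs file must have 7 or 9 tab-separated columns, got ", ncol(df))
  df
}

#' @rdname readPairsFile
#' @param pairs pairs data.frame.
#' @export
writePairsFile <- function(pairs, path) {
  keep <- intersect(c("read_id", "chrom1", "pos1", "strand1",
                      "chrom2", "pos2", "strand2", "frag1", "frag2"),
                    names(pairs))
  write.table(pairs[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Canonicalize pair orientation
#'
#' Stores each pair with its two ends in lexicographic genome order
#' (chromosome order of the fragment map, then position), so duplicate
#' detection and the inward/outward strand rules are independent of which
#' mate was read 1.  Rows are then sorted by the canonical key.
#'
#' @param pairs pairs data.frame.
#' @param chromOrder character vector giving the genome chromosome order.
#' @return reoriented, sorted pairs data.frame.
#' @export
canonicalizePairs <- function(pairs, chromOrder) {
  c1 <- match(pairs$chrom1, chromOrder)
  c2 <- match(pairs$chrom2, chromOrder)
  swap <- (c2 < c1) | (c1 == c2 & pairs$pos2 < pairs$pos1)
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- pairs[swap, c("chrom1", "pos1", "strand1")]
    pairs[swap, c("chrom1", "pos1", "strand1")] <-
      pairs[swap, c("chrom2", "pos2", "strand2")]
    pairs[swap, c("chrom2", "pos2", "strand2")] <- tmp
    if (all(c("frag1", "frag2") %in% names(pairs))) {
      tf <- pairs$frag1[swap]
      pairs$frag1[swap] <- pairs$frag2[swap]
      pairs$frag2[swap] <- tf
    }
  }
  o <- order(match(pairs$chrom1, chromOrder), pairs$pos1,
             match(pairs$chrom2, chromOrder), pairs$pos2,
             pairs$strand1, pairs$strand2)
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Annotate pairs with restriction-fragment assignments
#'
#' Fills, for each mate, the containing fragment id, the distances to the
#' upstream/downstream cut sites, and the fragment length.  Mates on
#' chromosomes absent from the fragment map are marked unmappable
#' (\code{NA} fragment) and are auto-flagged by \code{\link{applyFilters}}.
#'
#' @param pairs pairs data.frame (canonicalized or not).
#' @param fragmap a \code{\linkS4class{FragmentMap}}.
#' @return pairs with columns \code{frag1, up1, down1, len1, frag2, up2,
#'   down2, len2} added.
#' @export
annotateFragments <- function(pairs, fragmap) {
  ann1 <- .annotateMate(pairs$chrom1, pairs$pos1, fragmap)
  ann2 <- .annotateMate(pairs$chrom2, pairs$pos2, fragmap)
  pairs$frag1 <- ann1$fragment; pairs$up1 <- ann1$upstream
  pairs$down1 <- ann1$downstream; pairs$len1 <- ann1$len
  pairs$frag2 <- ann2$fragment; pairs$up2 <- ann2$upstream
  pairs$down2 <- ann2$downstream; pairs$len2 <- ann2$len
  pairs
}

.annotateMate <- function(chrom, pos, fragmap) {
  n <- length(chrom)
  out <- data.frame(fragment = rep(NA_integer_, n), upstream = NA_real_,
                    downstream = NA_real_, len = NA_real_)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    if (!chr %in% names(fragmap@seqlengths)) next
    loc <- locateFragment(fragmap, chr, pos[idx])
    out$fragment[idx] <- loc$fragment
    out$upstream[idx] <- loc$upstream
    out$downstream[idx] <- loc$downstream
    out$len[idx] <- loc$upstream + loc$downstream
  }
  out
}

#' Blacklist over-represented fragments
#'
#' Fragments whose pair count lies strictly above the
#' \code{1 - topFraction} quantile of per-fragment counts (over fragments
#' with at least one pair) are blacklisted; ties at the threshold are kept.
#'
#' @param pairs annotated pairs.
#' @param topFraction fraction of fragments to blacklist, in (0,1).
#' @return data.frame \code{chrom, fragment, count} of blacklisted fragments.
#' @export
flagOverRepresented <- function(pairs, topFraction = 0.005) {
  if (topFraction <= 0 || topFraction >= 1)
    stop("topFraction must lie in (0, 1)")
  keys <- c(paste(pairs$chrom1, pairs$frag1, sep = ":"),
            paste(pairs$chrom2, pairs$frag2, sep = ":"))
  keys <- keys[!grepl(":NA$", keys)]
  cnt <- table(keys)
  thr <- quantile(as.numeric(cnt), 1 - topFraction, names = FALSE)
  bad <- names(cnt)[as.numeric(cnt) > thr]
  if (length(bad) == 0L)
    return(data.frame(chrom = character(), fragment = integer(),
                      count = numeric()))
  parts <- strsplit(bad, ":")
  data.frame(chrom = vapply(parts, function(p)
               paste(p[-length(p)], collapse = ":"), ""),
             fragment = as.integer(vapply(parts, function(p) p[length(p)], "")),
             count = as.numeric(cnt[bad]))
}

#' Classify annotated pairs by the ten artifact criteria
#'
#' With pairs in canonical orientation, "inward" means strands (+,-) and
#' "outward" (-,+).  The criteria: (1) self-circle: same fragment, outward;
#' (2) dangling end: same fragment, inward; (3) error: same fragment, same
#' strand; (4) extra dangling end: different fragments, inward, separation
#' below \code{maxMoleculeLength}; (5) too close to a restriction site:
#' either 5' end nearer than \code{minDistToRe} to a cut; (6)/(7) fragment
#' shorter than \code{minFragSize} / longer than \code{maxFragSize};
#' (8) over-represented fragment (top \code{overRepFraction} quantile);
#' (9) duplicated canonical coordinates (first kept); (10) random break:
#' ligation-side cut distances summing above \code{maxMoleculeLength}.
#' A pair may carry several flags.
#'
#' @param pairs canonicalized, annotated pairs.
#' @param params list from \code{\link{filterParams}}.
#' @return logical matrix, one row per pair, columns the ten filters plus
#'   \code{unmapped}.
#' @export
classifyPairs <- function(pairs, params = filterParams()) {
  n <- nrow(pairs)
  fl <- matrix(FALSE, n, length(PAIR_FILTERS) + 1L,
               dimnames = list(NULL, c(PAIR_FILTERS, "unmapped")))
  unmapped <- is.na(pairs$frag1) | is.na(pairs$frag2)
  fl[, "unmapped"] <- unmapped
  same <- !unmapped & pairs$chrom1 == pairs$chrom2 & pairs$frag1 == pairs$frag2
  inward <- pairs$strand1 == "+" & pairs$strand2 == "-"
  outward <- pairs$strand1 == "-" & pairs$strand2 == "+"
  fl[, "self_circle"] <- same & outward
  fl[, "dangling_end"] <- same & inward
  fl[, "error"] <- same & pairs$strand1 == pairs$strand2
  fl[, "extra_dangling"] <- !unmapped & !same & pairs$chrom1 == pairs$chrom2 &
    inward & (pairs$pos2 - pairs$pos1) < params$maxMoleculeLength
  fl[, "too_close_re"] <- !unmapped &
    (pmin(pairs$up1, pairs$down1) < params$minDistToRe |
     pmin(pairs$up2, pairs$down2) < params$minDistToRe)
  fl[, "too_short"] <- !unmapped &
    (pairs$len1 < params$minFragSize | pairs$len2 < params$minFragSize)
  fl[, "too_large"] <- !unmapped &
    (pairs$len1 > params$maxFragSize | pairs$len2 > params$maxFragSize)
  black <- flagOverRepresented(pairs[!unmapped, , drop = FALSE],
                               params$overRepFraction)
  if (nrow(black)) {
    bk <- paste(black$chrom, black$fragment, sep = ":")
    fl[, "over_represented"] <- !unmapped &
      (paste(pairs$chrom1, pairs$frag1, sep = ":") %in% bk |
       paste(pairs$chrom2, pairs$frag2, sep = ":") %in% bk)
  }
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2)
  fl[, "duplicated"] <- duplicated(key)
  ## ligation-side cut distance: downstream for + reads, upstream for - reads.
  ## The sequenced-molecule size test applies to ligated (different-fragment)
  ## pairs; same-fragment geometries are classified by criteria 1-3.
  lig1 <- ifelse(pairs$strand1 == "+", pairs$down1, pairs$up1)
  lig2 <- ifelse(pairs$strand2 == "+", pairs$down2, pairs$up2)
  fl[, "random_break"] <- !unmapped & !same &
    (lig1 + lig2 > params$maxMoleculeLength)
  fl
}

#' Apply artifact filters to mapped pairs
#'
#' Canonicalizes, annotates and classifies the pairs, then removes every
#' pair carrying at least one enabled flag.  The report counts each filter
#' independently (a pair may be flagged by several criteria, so percentages
#' can sum above 100), while the valid count uses the union of enabled flags.
#'
#' @param pairs pairs data.frame.
#' @param fragmap a \code{\linkS4class{FragmentMap}}.
#' @param enabled character subset of the ten filter names to apply
#'   (default all).  Unmappable pairs are always removed.
#' @param params list from \code{\link{filterParams}}.
#' @return list with \code{valid} (pairs data.frame in canonical order),
#'   \code{report} (data.frame \code{filter, count, pct}), \code{input},
#'   \code{nValid}, and the full flag matrix \code{flags}.
#' @export
applyFilters <- function(pairs, fragmap, enabled = PAIR_FILTERS,
                         params = filterParams()) {
  enabled <- match.arg(enabled, PAIR_FILTERS, several.ok = TRUE)
  n <- nrow(pairs)
  if (n == 0L) {
    rep0 <- data.frame(filter = c(PAIR_FILTERS, "unmapped"),
                       count = 0L, pct = 0)
    return(list(valid = pairs, report = rep0, input = 0L, nValid = 0L,
                flags = matrix(FALSE, 0L, length(PAIR_FILTERS) + 1L)))
  }
  pairs <- canonicalizePairs(pairs, names(fragmap@seqlengths))
  pairs <- annotateFragments(pairs, fragmap)
  fl <- classifyPairs(pairs, params)
  drop <- rowSums(fl[, c(enabled, "unmapped"), drop = FALSE]) > 0
  report <- data.frame(filter = colnames(fl),
                       count = as.integer(colSums(fl)),
                       pct = 100 * colSums(fl) / n)
  list(valid = pairs[!drop, , drop = FALSE], report = report,
       input = n, nValid = sum(!drop), flags = fl)
}
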