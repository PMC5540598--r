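## Deterministic generators for every pipeline input: planted-artifact read
## pairs, distance-decay matrices with planted TAD blocks, and toy 3D
## structures with induced contact maps.  Every generator is a pure
## function of (parameters, seed) and returns a truth object that makes the
## downstream stage's output exactly predictable.

#' Simulate read pairs with planted artifact classes
#'
#' Constructs, per requested class, pairs whose geometry satisfies exactly
#' that one artifact definition (and none other) on the given fragment map,
#' so \code{\link{applyFilters}} recovers the planted counts exactly.
#' Requires a fragment map with enough "normal" fragments (length 300 bp to
#' \code{maxFragSize}) on at least two chromosomes, plus a short
#' (< \code{minFragSize}) and an over-long fragment when those classes are
#' requested.
#'
#' @param fragmap a \code{\linkS4class{FragmentMap}}.
#' @param classCounts named integer vector over \code{"valid"} and the
#'   filter names of \code{\link{classifyPairs}} (e.g.
#'   \code{c(valid = 90, dangling_end = 10)}).
#' @param params list from \code{\link{filterParams}}.
#' @param seed integer seed (controls output shuffling only; geometry is
#'   deterministic).
#' @return list \code{pairs} (pairs data.frame), \code{truth} (data.frame
#'   \code{read_id, class}), \code{seed}.
#' @export
simulatePairs <- function(fragmap, classCounts, params = filterParams(),
                          seed = 1L) {
  ft <- fragmentTable(fragmap)
  ft$len <- ft$end - ft$start
  normal <- ft[ft$len >= 300 & ft$len <= params$maxFragSize, , drop = FALSE]
  chroms <- unique(normal$chrom)
  if (length(chroms) < 2L)
    stop("generation error: need normal fragments on >= 2 chromosomes")
  poolA <- normal[normal$chrom == chroms[1L], , drop = FALSE]
  poolB <- normal[normal$chrom == chroms[2L], , drop = FALSE]
  cntA <- 0L; cntB <- 0L
  nextA <- function() { cntA <<- cntA + 1L; poolA[(cntA - 1L) %% nrow(poolA) + 1L, ] }
  nextB <- function() { cntB <<- cntB + 1L; poolB[(cntB - 1L) %% nrow(poolB) + 1L, ] }
  ## reserve one fragment for the over-represented class
  overFrag <- poolA[nrow(poolA), ]
  poolA <- poolA[-nrow(poolA), , drop = FALSE]
  offs <- function(k) 50 + (k %% 140)        # distinct in-fragment offsets
  rows <- list(); classes <- character(0)
  emit <- function(chrom1, pos1, strand1, chrom2, pos2, strand2, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
      chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
      stringsAsFactors = FALSE)
    classes <<- c(classes, class)
  }
  want <- function(cl) if (cl %in% names(classCounts))
    as.integer(classCounts[[cl]]) else 0L

  validRows <- list()
  for (k in seq_len(want("valid"))) {
    ## Latin-square indexing: fragment pairs stay distinct while the load
    ## spreads evenly over both pools (no accidental over-representation)
    ka <- (k - 1L) %% nrow(poolA)
    fa <- poolA[ka + 1L, ]
    fb <- poolB[(ka + (k - 1L) %/% nrow(poolA)) %% nrow(poolB) + 1L, ]
    o1 <- offs(k); o2 <- offs(k + 7L)
    s1 <- c("+", "-", "+", "-")[k %% 4L + 1L]
    s2 <- c("+", "+", "-", "-")[k %% 4L + 1L]
    p1 <- if (s1 == "+") fa$end - o1 else fa$start + o1
    p2 <- if (s2 == "+") fb$end - o2 else fb$start + o2
    emit(fa$chrom, p1, s1, fb$chrom, p2, s2, "valid")
    validRows[[k]] <- rows[[length(rows)]]
  }
  for (k in seq_len(want("self_circle"))) {
    f <- nextA()
    emit(f$chrom, f$start + offs(k), "-", f$chrom, f$end - offs(k + 3L), "+",
         "self_circle")
  }
  for (k in seq_len(want("dangling_end"))) {
    f <- nextA()
    emit(f$chrom, f$start + offs(k), "+", f$chrom, f$end - offs(k + 3L), "-",
         "dangling_end")
  }
  for (k in seq_len(want("error"))) {
    f <- nextA()
    emit(f$chrom, f$start + offs(k), "+", f$chrom, f$end - offs(k + 3L), "+",
         "error")
  }
  if (want("extra_dangling") > 0L) {
    adj <- which(diff(poolA$fragment_id) == 1L)
    if (!length(adj)) stop("generation error: extra_dangling needs adjacent fragments")
    for (k in seq_len(want("extra_dangling"))) {
      a <- poolA[adj[(k - 1L) %% length(adj) + 1L], ]
      cut <- a$end
      emit(a$chrom, cut - offs(k), "+", a$chrom, cut + offs(k + 3L), "-",
           "extra_dangling")
    }
  }
  for (k in seq_len(want("too_close_re"))) {
    fa <- nextA(); fb <- nextB()
    emit(fa$chrom, fa$start + 2, "-", fb$chrom, fb$start + offs(k), "-",
         "too_close_re")
  }
  if (want("too_short") > 0L) {
    shorts <- ft[ft$len >= 2 * params$minDistToRe + 1 &
                 ft$len < params$minFragSize, , drop = FALSE]
    if (!nrow(shorts)) stop("generation error: too_short needs a fragment < minFragSize")
    for (k in seq_len(want("too_short"))) {
      f <- shorts[(k - 1L) %% nrow(shorts) + 1L, ]
      fb <- nextB()
      emit(f$chrom, f$start + f$len %/% 2, "-",
           fb$chrom, fb$start + offs(k), "-", "too_short")
    }
  }
  if (want("too_large") > 0L) {
    larges <- ft[ft$len > params$maxFragSize, , drop = FALSE]
    if (!nrow(larges)) stop("generation error: too_large needs a fragment > maxFragSize")
    for (k in seq_len(want("too_large"))) {
      f <- larges[(k - 1L) %% nrow(larges) + 1L, ]
      fb <- nextB()
      emit(f$chrom, f$end - offs(k), "+", fb$chrom, fb$start + offs(k + 3L),
           "-", "too_large")
    }
  }
  for (k in seq_len(want("over_represented"))) {
    fb <- nextB()
    emit(overFrag$chrom, overFrag$start + 5 + 2 * k, "-",
         fb$chrom, fb$start + offs(k), "-", "over_represented")
  }
  for (k in seq_len(want("duplicated"))) {
    if (!length(validRows)) stop("generation error: duplicated needs valid pairs to copy")
    src <- validRows[[(k - 1L) %% length(validRows) + 1L]]
    emit(src$chrom1, src$pos1, src$strand1, src$chrom2, src$pos2,
         src$strand2, "duplicated")
  }
  for (k in seq_len(want("random_break"))) {
    fa <- nextA(); fb <- nextB()
    d1 <- min(400, fa$len - 10); d2 <- min(400, fb$len - 10)
    if (d1 + d2 <= params$maxMoleculeLength)
      stop("generation error: random_break needs longer fragments")
    emit(fa$chrom, fa$end - d1, "+", fb$chrom, fb$end - d2, "+",
         "random_break")
  }
  df <- do.call(rbind, rows)
  df <- cbind(read_id = sprintf("sim_%05d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  truth <- data.frame(read_id = df$read_id, class = classes,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  o <- sample.int(nrow(df))
  list(pairs = df[o, , drop = FALSE], truth = truth[o, , drop = FALSE],
       seed = seed)
}

#' Simulate a distance-decay matrix with planted TAD blocks
#'
#' \code{counts[i, j] ~ Poisson(depth * max(|i-j|, 1)^(-decayExponent) * f)}
#' with \code{f = intraFactor} when i and j fall in the same planted TAD and
#' 1 otherwise; symmetric (upper triangle drawn, mirrored).
#'
#' @param nBins matrix size.
#' @param borders planted internal TAD start bins (sorted, within
#'   \code{2..nBins}); the first TAD always starts at bin 1.
#' @param intraFactor intra-TAD enrichment (1 = no block structure).
#' @param decayExponent power-law decay exponent.
#' @param depth expected count at distance 1.
#' @param seed integer seed.
#' @return list \code{counts}, \code{truth} (borders, intraFactor,
#'   decayExponent, depth, seed).
#' @export
simulateMatrix <- function(nBins, borders = integer(), intraFactor = 1,
                           decayExponent = 1, depth = 100, seed = 1L) {
  stopifnot(all(borders >= 2), all(borders <= nBins))
  set.seed(seed)
  tad <- findInterval(seq_len(nBins), c(1L, sort(borders)))
  d <- abs(outer(seq_len(nBins), seq_len(nBins), `-`))
  f <- ifelse(outer(tad, tad, `==`), intraFactor, 1)
  lambda <- depth * pmax(d, 1)^(-decayExponent) * f
  up <- upper.tri(lambda, diag = TRUE)
  counts <- matrix(0, nBins, nBins)
  counts[up] <- rpois(sum(up), lambda[up])
  counts <- counts + t(counts) - diag(diag(counts))
  list(counts = counts,
       truth = list(borders = sort(borders), intraFactor = intraFactor,
                    decayExponent = decayExponent, depth = depth,
                    seed = seed))
}

#' Toy 3D structures
#'
#' Deterministic chains with constant consecutive spacing: a straight line,
#' a closed-form helix (fixed angular step per particle), or a seeded
#' fixed-step random walk.
#'
#' @param kind \code{"straight"}, \code{"helix"} or \code{"random_walk"}.
#' @param n particle count (>= 3).
#' @param step consecutive particle spacing (nm).
#' @param seed seed (random walk only).
#' @param helixRadius helix radius (nm); must not exceed
#'   \code{step / (2 * sin(dtheta / 2))}.
#' @param dtheta angular step of the helix (radians).
#' @return n x 3 coordinate matrix (nm).
#' @export
toyStructure <- function(kind = c("straight", "helix", "random_walk"),
                         n, step = 100, seed = 1L, helixRadius = step,
                         dtheta = pi / 6) {
  kind <- match.arg(kind)
  stopifnot(n >= 3L)
  if (kind == "straight") {
    return(cbind((seq_len(n) - 1L) * step, 0, 0))
  }
  if (kind == "helix") {
    chord <- 2 * helixRadius * sin(dtheta / 2)
    if (chord > step) stop("helixRadius too large for the given step")
    dz <- sqrt(step^2 - chord^2)
    th <- (seq_len(n) - 1L) * dtheta
    return(cbind(helixRadius * cos(th), helixRadius * sin(th),
                 (seq_len(n) - 1L) * dz))
  }
  set.seed(seed)
  dirs <- matrix(rnorm(3L * (n - 1L)), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbind(c(0, 0, 0), apply(dirs * step, 2L, cumsum))
}

#' Contact matrix induced by a 3D structure
#'
#' \code{counts[i, j] ~ Poisson(depth * p_ij)} with contact probability
#' \code{p_ij = logistic((dcutoff - d_ij) / (noise * dcutoff))}; with
#' \code{noise = 0} the probability is the hard indicator
#' \code{d_ij < dcutoff}.  Rigid transforms of the coordinates leave the
#' matrix distribution unchanged (distances are invariant).
#'
#' @param coords n x 3 coordinates (nm).
#' @param dcutoff contact distance (nm).
#' @param depth expected count of a certain contact.
#' @param noise logistic width as a fraction of \code{dcutoff} (default
#'   0.1; 0 = hard threshold).
#' @param seed integer seed.
#' @return list \code{counts}, \code{prob}, \code{truth} (coords, dcutoff,
#'   depth, noise, seed).
#' @export
structureToMatrix <- function(coords, dcutoff, depth = 100, noise = 0.1,
                              seed = 1L) {
  stopifnot(all(is.finite(coords)))
  d <- unname(as.matrix(dist(coords)))
  p <- if (noise <= 0) (d < dcutoff) * 1
       else 1 / (1 + exp(-(dcutoff - d) / (noise * dcutoff)))
  set.seed(seed)
  n <- nrow(coords)
  up <- upper.tri(p, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- rpois(sum(up), depth * p[up])
  counts <- counts + t(counts) - diag(diag(counts))
  list(counts = counts, prob = p,
       truth = list(coords = coords, dcutoff = dcutoff, depth = depth,
                    noise = noise, seed = seed))
}

#' Synthetic two-chromosome test genome
#'
#' Builds a deterministic genome whose HindIII-style digestion yields the
#' fragment classes \code{\link{simulatePairs}} needs: many normal
#' fragments (~500 bp) on two chromosomes, one short (< 50 bp) and one
#' over-long (> \code{largeLen} bp) fragment.
#'
#' @param motif restriction motif planted between fragments.
#' @param nFrags normal fragments per chromosome.
#' @param fragLen normal fragment length (bp).
#' @param largeLen length of the over-long fragment (bp).
#' @param seed seed for the random sequence fill.
#' @return named character vector of chromosome sequences.
#' @export
syntheticGenome <- function(motif = "AAGCTT", nFrags = 60L, fragLen = 500L,
                            largeLen = 120000L, seed = 1L) {
  set.seed(seed)
  fill <- function(len) {
    ## random sequence with every motif occurrence disrupted in place
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    str <- paste(s, collapse = "")
    repeat {
      hit <- regexpr(motif, str, fixed = TRUE)
      if (hit == -1L) return(str)
      pos <- as.integer(hit)
      old <- substr(str, pos, pos)
      substr(str, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1L]
    }
  }
  L <- nchar(motif)
  seg <- function(len) fill(len - L)       # fragment body before next motif
  chrA <- paste0(paste(vapply(seq_len(nFrags), function(i) paste0(seg(fragLen), motif),
                              ""), collapse = ""),
                 fill(20L), motif,          # short fragment (20 + motif tail)
                 fill(300L))
  chrB <- paste0(paste(vapply(seq_len(nFrags), function(i) paste0(seg(fragLen), motif),
                              ""), collapse = ""),
                 fill(largeLen))            # over-long terminal fragment
  c(chrA = chrA, chrB = chrB)
}
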