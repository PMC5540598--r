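fmapFixture <- local({
  fm <- NULL
  function() {
    if (is.null(fm)) fm <<- digestGenome(syntheticGenome(seed = 3), "AAGCTT", 1)
    fm
  }
})

test_that("same-fragment strand geometry is classified definitionally", {
  fm <- fmapFixture()
  ft <- fragmentTable(fm)
  ft$len <- ft$end - ft$start
  f <- ft[ft$len >= 300 & ft$len <= 1e5, ][1, ]
  mk <- function(s1, s2) data.frame(
    read_id = "r", chrom1 = f$chrom, pos1 = f$start + 100, strand1 = s1,
    chrom2 = f$chrom, pos2 = f$end - 100, strand2 = s2)
  cls <- function(p) {
    p <- annotateFragments(p, fm)
    fl <- classifyPairs(p)
    colnames(fl)[fl[1, ]]
  }
  expect_equal(cls(mk("+", "-")), "dangling_end")   # inward
  expect_equal(cls(mk("-", "+")), "self_circle")    # outward
  expect_equal(cls(mk("+", "+")), "error")          # same strand
  expect_equal(cls(mk("-", "-")), "error")
})

test_that("fragment annotation equals the linear-scan oracle", {
  fm <- fmapFixture()
  set.seed(5)
  lens <- fm@seqlengths
  n <- 500
  pr <- data.frame(
    read_id = paste0("r", 1:n),
    chrom1 = sample(names(lens), n, TRUE), pos1 = NA, strand1 = "+",
    chrom2 = sample(names(lens), n, TRUE), pos2 = NA, strand2 = "-")
  pr$pos1 <- floor(runif(n) * lens[pr$chrom1])
  pr$pos2 <- floor(runif(n) * lens[pr$chrom2])
  ann <- annotateFragments(pr, fm)
  for (k in sample(n, 40)) {
    want <- scanLocate(fm@cuts[[pr$chrom1[k]]], lens[[pr$chrom1[k]]], pr$pos1[k])
    expect_equal(ann$frag1[k], want$fragment)
    expect_equal(ann$up1[k], want$up)
    expect_equal(ann$down1[k], want$down)
  }
})

test_that("planted artifact classes are recovered exactly", {
  fm <- fmapFixture()
  cc <- c(valid = 700, self_circle = 50, dangling_end = 60, error = 30,
          extra_dangling = 40, too_close_re = 30, too_short = 20,
          too_large = 20, over_represented = 25, duplicated = 15,
          random_break = 10)
  sim <- simulatePairs(fm, cc, seed = 2)
  res <- applyFilters(sim$pairs, fm)
  got <- setNames(res$report$count, res$report$filter)
  for (cl in setdiff(names(cc), "valid"))
    expect_equal(unname(got[cl]), unname(cc[cl]), label = cl)
  expect_equal(res$nValid, unname(cc["valid"]))
  # conservation under union accounting
  expect_equal(res$nValid + sum(rowSums(res$flags) > 0), res$input)
})

test_that("classification is orientation-independent and idempotent", {
  fm <- fmapFixture()
  sim <- simulatePairs(fm, c(valid = 50, self_circle = 10), seed = 4)
  p <- sim$pairs
  # swap mates of every pair: canonicalization must undo it
  sw <- p
  sw[, c("chrom1", "pos1", "strand1")] <- p[, c("chrom2", "pos2", "strand2")]
  sw[, c("chrom2", "pos2", "strand2")] <- p[, c("chrom1", "pos1", "strand1")]
  r1 <- applyFilters(p, fm)
  r2 <- applyFilters(sw, fm)
  expect_equal(r1$report, r2$report)
  # filtering the valid output again removes nothing
  r3 <- applyFilters(r1$valid[, 1:7], fm)
  expect_equal(r3$nValid, r1$nValid)
})

test_that("disabling filters never decreases the valid count", {
  fm <- fmapFixture()
  sim <- simulatePairs(fm, c(valid = 200, self_circle = 30, dangling_end = 30,
                             random_break = 10), seed = 6)
  all10 <- applyFilters(sim$pairs, fm)$nValid
  for (drop in c("self_circle", "dangling_end", "random_break")) {
    sub <- applyFilters(sim$pairs, fm,
                        enabled = setdiff(tadmod:::PAIR_FILTERS, drop))$nValid
    expect_gte(sub, all10)
  }
  none <- applyFilters(sim$pairs, fm, enabled = "duplicated")$nValid
  expect_gte(none, all10)
})

test_that("over-representation uses a strict quantile (ties survive)", {
  fm <- fmapFixture()
  # equal counts on every fragment: nothing strictly above the quantile
  sim <- simulatePairs(fm, c(valid = 120), seed = 8)
  p <- annotateFragments(canonicalizePairs(sim$pairs, names(fm@seqlengths)), fm)
  even <- flagOverRepresented(p, 0.005)
  expect_equal(nrow(even), 0L)
  # one fragment holding half of all pairs is blacklisted
  half <- p
  half$chrom1 <- p$chrom1[1]; half$frag1 <- p$frag1[1]
  mixed <- rbind(p, half)
  bl <- flagOverRepresented(mixed, 0.005)
  expect_true(nrow(bl) >= 1L)
  expect_true(p$frag1[1] %in% bl$fragment[bl$chrom == p$chrom1[1]])
  expect_error(flagOverRepresented(p, 0), "\\(0, 1\\)")
})

test_that("empty input yields an empty report", {
  fm <- fmapFixture()
  empty <- data.frame(read_id = character(), chrom1 = character(),
                      pos1 = numeric(), strand1 = character(),
                      chrom2 = character(), pos2 = numeric(),
                      strand2 = character())
  res <- applyFilters(empty, fm)
  expect_equal(res$input, 0L)
  expect_equal(res$nValid, 0L)
  expect_true(all(res$report$count == 0L))
})

test_that("pairs text format round-trips including comments and gzip", {
  fm <- fmapFixture()
  sim <- simulatePairs(fm, c(valid = 20), seed = 10)
  f <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(f, "w")
  writeLines("# pairs-like file", con)
  close(con)
  con <- gzfile(f, "a")
  utils::write.table(sim$pairs[, 1:7], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  back <- readPairsFile(f)
  expect_equal(back$pos1, sim$pairs$pos1)
  expect_equal(back$chrom2, sim$pairs$chrom2)
})
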