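## End-to-end orchestration from a single YAML config: stages are executed
## in dependency order, every output file is listed in a JSON manifest with
## the parameters and seeds actually used, and deterministic stages
## reproduce byte-identical outputs for the same config.

PIPELINE_STAGES <- c("simulate", "qc", "filter", "bin", "normalize",
                     "compare", "segment", "align_borders", "model",
                     "analyze")

.cfgGet <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

.checkKeys <- function(cfg, allowed, where) {
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ", paste(extra, collapse = ", "))
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in order on shared intermediate state and
#' writes each stage's outputs under \code{outdir}.  The returned (and
#' written) manifest records every parameter actually used, including
#' defaults, and the global seed, sufficient to re-run the pipeline.
#'
#' @param config path to a YAML file or an equivalent named list.  Top-level
#'   keys: \code{outdir}, \code{seed}, \code{stages} (subset of
#'   \code{simulate, qc, filter, bin, normalize, compare, segment,
#'   align_borders, model, analyze}), \code{genome} (\code{fasta} path),
#'   \code{enzyme} (\code{motif}, \code{cut}), plus one section per stage.
#'   Unknown keys are rejected.
#' @return the manifest list, invisibly (also written to
#'   \code{outdir/manifest.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .checkKeys(config, c("outdir", "seed", "stages", "genome", "enzyme",
                       PIPELINE_STAGES), "top level")
  outdir <- .cfgGet(config, "outdir", ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfgGet(config, "seed", 1L))
  stages <- .cfgGet(config, "stages", character())
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]   # dependency order

  state <- new.env(parent = emptyenv())
  manifest <- list(seed = seed, stages = stages, outputs = list(),
                   params = list())
  note <- function(stage, params, files) {
    manifest$params[[stage]] <<- params
    manifest$outputs[[stage]] <<- files
  }
  enz <- .cfgGet(config, "enzyme", list(motif = "AAGCTT", cut = 1L))
  if (!is.null(config$genome$fasta)) {
    state$genome <- readGenome(config$genome$fasta)
    state$fragmap <- digestGenome(state$genome, enz$motif, enz$cut)
  }

  for (stage in stages) {
    cfg <- .cfgGet(config, stage, list())
    res <- try(switch(stage,
      simulate = .stageSimulate(cfg, state, outdir, seed, note),
      qc = .stageQc(cfg, state, outdir, enz, note),
      filter = .stageFilter(cfg, state, outdir, note),
      bin = .stageBin(cfg, state, outdir, note),
      normalize = .stageNormalize(cfg, state, outdir, note),
      compare = .stageCompare(cfg, state, outdir, note),
      segment = .stageSegment(cfg, state, outdir, note),
      align_borders = .stageAlign(cfg, state, outdir, note),
      model = .stageModel(cfg, state, outdir, seed, note),
      analyze = .stageAnalyze(cfg, state, outdir, note)), silent = TRUE)
    if (inherits(res, "try-error"))
      stop("stage '", stage, "' failed: ", attr(res, "condition")$message)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.stageSimulate <- function(cfg, state, outdir, seed, note) {
  .checkKeys(cfg, c("what", "classCounts", "nBins", "borders", "intraFactor",
                    "depth", "genomeSeed"), "simulate")
  what <- .cfgGet(cfg, "what", "pairs")
  files <- character()
  if (what == "pairs") {
    if (is.null(state$fragmap)) {
      g <- syntheticGenome(seed = .cfgGet(cfg, "genomeSeed", seed))
      state$genome <- g
      state$fragmap <- digestGenome(g, "AAGCTT", 1L)
    }
    cc <- unlist(.cfgGet(cfg, "classCounts", list(valid = 200)))
    sim <- simulatePairs(state$fragmap, cc, seed = seed)
    state$pairs <- sim$pairs
    f <- file.path(outdir, "simulated_pairs.tsv")
    writePairsFile(sim$pairs, f)
    files <- f
  } else if (what == "matrix") {
    sim <- simulateMatrix(.cfgGet(cfg, "nBins", 100L),
                          .cfgGet(cfg, "borders", integer()),
                          .cfgGet(cfg, "intraFactor", 3),
                          depth = .cfgGet(cfg, "depth", 100), seed = seed)
    state$regionCounts <- sim$counts
    f <- file.path(outdir, "simulated_matrix.tsv")
    write.table(sim$counts, f, sep = "\t", row.names = FALSE,
                col.names = FALSE)
    files <- f
  } else stop("simulate.what must be 'pairs' or 'matrix'")
  note("simulate", cfg, files)
}

.stageQc <- function(cfg, state, outdir, enz, note) {
  .checkKeys(cfg, c("fastq", "nReads", "phredOffset"), "qc")
  if (is.null(cfg$fastq)) stop("qc stage needs a fastq path")
  n <- .cfgGet(cfg, "nReads", 1e6)
  rep <- c(qualityProfile(cfg$fastq, n, .cfgGet(cfg, "phredOffset", 33L)),
           ligationStats(cfg$fastq, enz$motif, enz$cut, n))
  f <- file.path(outdir, "qc_report.json")
  writeQcReport(rep, f)
  note("qc", c(cfg, enz), f)
}

.stageFilter <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("pairs", "drop", names(filterParams())), "filter")
  if (is.null(state$pairs)) {
    if (is.null(cfg$pairs)) stop("filter stage needs pairs (file or simulate stage)")
    state$pairs <- readPairsFile(cfg$pairs)
  }
  if (is.null(state$fragmap)) stop("filter stage needs a genome/fragment map")
  params <- do.call(filterParams,
                    cfg[intersect(names(cfg), names(filterParams()))])
  enabled <- .cfgGet(cfg, "drop", PAIR_FILTERS)
  res <- applyFilters(state$pairs, state$fragmap, enabled, params)
  state$valid <- res$valid
  fv <- file.path(outdir, "valid_pairs.tsv")
  writePairsFile(res$valid, fv)
  fr <- file.path(outdir, "filter_report.json")
  jsonlite::write_json(list(input = res$input, valid = res$nValid,
                            report = res$report), fr,
                       auto_unbox = TRUE, digits = NA)
  note("filter", c(params, list(drop = enabled)), c(fv, fr))
}

.stageBin <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("resolution"), "bin")
  if (is.null(state$valid)) stop("bin stage needs filtered pairs")
  res <- .cfgGet(cfg, "resolution", 1e4)
  lens <- if (!is.null(state$fragmap)) state$fragmap@seqlengths else
    stop("bin stage needs genome lengths")
  state$matrix <- binPairs(state$valid, lens, res)
  f <- file.path(outdir, "raw_matrix.tsv")
  writeHiCMatrix(state$matrix, f)
  note("bin", list(resolution = res), f)
}

.stageNormalize <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("maxDev", "maxIter"), "normalize")
  if (is.null(state$matrix)) stop("normalize stage needs a binned matrix")
  maxDev <- .cfgGet(cfg, "maxDev", 0.10)
  m <- maskColumns(state$matrix)
  m <- iceNormalize(m, maxDev, .cfgGet(cfg, "maxIter", 100L))
  state$normalized <- m
  f <- file.path(outdir, "normalized_matrix.tsv")
  writeHiCMatrix(m, f)
  note("normalize", list(maxDev = maxDev), f)
}

.stageCompare <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("matrices", "maxDist", "k"), "compare")
  if (is.null(cfg$matrices) || length(cfg$matrices) != 2L)
    stop("compare stage needs exactly two matrix files")
  A <- readHiCMatrix(cfg$matrices[[1L]])
  B <- readHiCMatrix(cfg$matrices[[2L]])
  maxDist <- .cfgGet(cfg, "maxDist", 100L)
  k <- .cfgGet(cfg, "k", 3L)
  rho <- spearmanByDistance(A, B, maxDist)
  ec <- eigenCorrelation(A, B, k)
  f <- file.path(outdir, "comparison.json")
  jsonlite::write_json(list(spearmanByDistance = rho, eigenCorrelation = ec),
                       f, auto_unbox = TRUE, digits = NA)
  note("compare", list(maxDist = maxDist, k = k), f)
}

.stageSegment <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("maxTadBins", "minTadBins", "forceM", "resolution",
                    "chrom"), "segment")
  mat <- if (!is.null(state$normalized)) state$normalized else
    state$regionCounts
  if (is.null(mat)) stop("segment stage needs a matrix")
  if (is(mat, "HiCMatrix") && length(mat@chromNames) > 1L)
    mat <- chromosomeSubmatrix(mat, .cfgGet(cfg, "chrom", mat@chromNames[1L]))
  args <- list(mat = mat,
               maxTadBins = .cfgGet(cfg, "maxTadBins", 300L),
               minTadBins = .cfgGet(cfg, "minTadBins", 2L))
  if (!is.null(cfg$forceM)) args$forceM <- cfg$forceM
  if (!is.null(cfg$resolution)) args$resolution <- cfg$resolution
  seg <- do.call(optimalSegmentation, args)
  state$segmentation <- seg
  f <- file.path(outdir, "tads.tsv")
  writeBorders(seg, f)
  note("segment", args[-1L], f)
}

.stageAlign <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("borders", "maxDist", "gapPenalty", "tolerance"),
             "align_borders")
  if (is.null(cfg$borders) || length(cfg$borders) < 2L)
    stop("align_borders stage needs >= 2 border files")
  lists <- lapply(cfg$borders, readBorderBed)
  names(lists) <- basename(unlist(cfg$borders))
  maxDist <- .cfgGet(cfg, "maxDist", 1e5)
  tol <- .cfgGet(cfg, "tolerance", 2e4)
  al <- alignBordersNW(lists[[1L]], lists[[2L]], maxDist,
                       .cfgGet(cfg, "gapPenalty", 0.2))
  f <- file.path(outdir, "border_alignment.json")
  jsonlite::write_json(list(
    agreementA = borderAgreement(al, tol, "a"),
    agreementB = borderAgreement(al, tol, "b"),
    columns = al$columns), f, auto_unbox = TRUE, digits = NA)
  note("align_borders", list(maxDist = maxDist, tolerance = tol), f)
}

.stageModel <- function(cfg, state, outdir, seed, note) {
  .checkKeys(cfg, c("resolution", "nCompute", "nKeep", "nSweeps", "lowfreq",
                    "upfreq", "maxdist"), "model")
  mat <- if (!is.null(state$normalized)) state$normalized else
    state$regionCounts
  if (is.null(mat)) stop("model stage needs a matrix")
  if (is(mat, "HiCMatrix") && length(mat@chromNames) > 1L)
    mat <- chromosomeSubmatrix(mat, mat@chromNames[1L])
  p <- modelingParams(resolution = .cfgGet(cfg, "resolution", 1e4),
                      lowfreq = .cfgGet(cfg, "lowfreq", -0.6),
                      upfreq = .cfgGet(cfg, "upfreq", 0.3),
                      maxdist = .cfgGet(cfg, "maxdist", 1500))
  z <- zscoreMatrix(mat)
  rs <- buildRestraints(z, p)
  ens <- generateEnsemble(rs, nCompute = .cfgGet(cfg, "nCompute", 60L),
                          nKeep = .cfgGet(cfg, "nKeep", 50L),
                          baseSeed = seed, params = p,
                          nSweeps = .cfgGet(cfg, "nSweeps", 500L))
  state$ensemble <- ens
  d <- file.path(outdir, "models")
  writeEnsembleXyz(ens, d)
  note("model", p, d)
}

.stageAnalyze <- function(cfg, state, outdir, note) {
  .checkKeys(cfg, c("cutoff", "probeRadius", "nMesh", "w", "colors",
                    "chrom", "start"), "analyze")
  if (is.null(state$ensemble)) stop("analyze stage needs a model ensemble")
  cutoff <- .cfgGet(cfg, "cutoff", 250)
  prof <- structuralProfile(state$ensemble, cutoff = cutoff,
                            probeRadius = .cfgGet(cfg, "probeRadius", 75),
                            nMesh = .cfgGet(cfg, "nMesh", 100L),
                            w = .cfgGet(cfg, "w", 3L))
  if (!is.null(cfg$colors)) {
    res <- state$ensemble@params$resolution
    start <- .cfgGet(cfg, "start", 0)
    bs <- start + (prof$particle - 1L) * res
    prof$color <- assignColors(bs, bs + res, cfg$colors,
                               .cfgGet(cfg, "chrom", "chrA"))
  }
  f <- file.path(outdir, "structural_profile.tsv")
  write.table(prof, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("analyze", list(cutoff = cutoff), f)
}
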