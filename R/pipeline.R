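## Orchestration: each run* function executes one stage of the analysis
## end to end and writes its tables (TSV with `#` provenance headers) to
## an output directory, returning the in-memory results invisibly. These
## functions, together with the package API, are the pipeline interface.

.paramDigest <- function(config) {
  flat <- config[!vapply(config, is.object, logical(1))]
  flat <- flat[!vapply(flat, is.data.frame, logical(1))]
  paste(names(flat), vapply(flat, function(v) paste(format(v), collapse = ","),
                            character(1)),
        sep = "=", collapse = ";")
}

.writeReport <- function(tab, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mtbreaks %s",
                     as.character(utils::packageVersion("mtbreaks"))), con)
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]])), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a paired native/S1 fragment-library experiment
#'
#' Generates one molecule population under `config`, derives the native
#' library from it directly and the S1-treated library from an S1-treated
#' copy of the same molecules, and writes `native.tsv`, `s1.tsv`, a
#' `truth.tsv` of the planted hotspots, and a `manifest.txt` recording
#' seed and parameters. Reruns with the same config are identical.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, `list(native, s1, truth, paths)`.
#' @export
runSimulate <- function(config, outDir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  mols <- simulateMolecules(config, seed = NULL)
  native <- .assembleLibrary(mols, config)
  s1 <- .assembleLibrary(lapply(mols, s1Treat), config)
  meta <- list(seed = config$seed, params = .paramDigest(config))
  paths <- file.path(outDir, c("native.tsv", "s1.tsv", "truth.tsv",
                               "manifest.txt"))
  writeFragmentTable(native, paths[1], meta = c(meta, library = "native"))
  writeFragmentTable(s1, paths[2], meta = c(meta, library = "s1"))
  .writeReport(config$hotspots, paths[3], meta = meta)
  writeLines(c(sprintf("mtbreaks %s",
                       as.character(utils::packageVersion("mtbreaks"))),
               sprintf("seed\t%d", config$seed),
               sprintf("params\t%s", .paramDigest(config))), paths[4])
  invisible(list(native = native, s1 = s1, truth = config$hotspots,
                 paths = paths))
}

#' Profile fragment ends and call break hotspots
#'
#' Runs the full calling chain on a native library and (optionally) its
#' S1-treated pair: end extraction with the restriction-site exclusion,
#' binning, depth normalization, SSB differential, circular
#' running-median background subtraction, top-bin ranking with region
#' exclusion, break-class assignment, and (when the genome carries a
#' sequence) GC/G4 motif annotation. Writes `profile.tsv`,
#' `hotspots.tsv` and, for paired input, `ssb.tsv` with clamping
#' diagnostics.
#'
#' @param native native fragment table, or path to one.
#' @param s1 S1-treated fragment table or path, or `NULL` for native-only
#'   profiling (DSB output only).
#' @param genome a [CircularGenome-class]; its regions supply the
#'   exclusion window (`EagI_exclusion`) and the ranking exclusions.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param binWidth bin width in bp.
#' @param windowHalfwidth background-median half-width in bins.
#' @param nTop number of hotspot bins to report per end class.
#' @param excludeLabels region labels excluded from ranking.
#' @param rankOn rank residuals of the `"s1"` (default, when paired) or
#'   `"native"` profile.
#' @param flank motif annotation flank in bp.
#' @return invisibly, a list with the profiles, residuals, SSB profile
#'   and the annotated hotspot calls (`callsUpstream`,
#'   `callsDownstream`).
#' @export
runProfileAndCall <- function(native, s1 = NULL, genome, outDir = NULL,
                              binWidth = 40L, windowHalfwidth = 25L,
                              nTop = 15L,
                              excludeLabels = c("D-loop", "oriL"),
                              rankOn = c("s1", "native"), flank = 0L) {
  stopifnot(is(genome, "CircularGenome"))
  rankOn <- match.arg(rankOn)
  if (is.character(native)) native <- readFragmentTable(native)
  if (is.character(s1)) s1 <- readFragmentTable(s1)
  L <- genomeLength(genome)
  rg <- regions(genome)
  exRow <- rg[rg$label == "EagI_exclusion", , drop = FALSE]
  exclusion <- if (nrow(exRow)) c(exRow$start[1], exRow$end[1]) else NULL
  rankExclude <- rg[rg$label %in% excludeLabels, , drop = FALSE]

  profileOf <- function(frags, cond, s1Flag) {
    ends <- extractEnds(frags, L, exclusion = exclusion, condition = cond,
                        s1Treated = s1Flag)
    prof <- binEnds(ends, binWidth)
    normalizeToDepth(prof, meanDepth(frags, L))
  }
  nativeProf <- profileOf(native, "native", FALSE)
  s1Prof <- if (!is.null(s1)) profileOf(s1, "s1", TRUE) else NULL
  ssb <- if (!is.null(s1Prof)) ssbDifferential(s1Prof, nativeProf) else NULL

  rankProf <- if (rankOn == "s1" && !is.null(s1Prof)) s1Prof else nativeProf
  res <- backgroundSubtract(rankProf, windowHalfwidth)
  nativeRes <- backgroundSubtract(nativeProf, windowHalfwidth)
  callsUp <- rankTopBins(res, "upstream", exclude = rankExclude, nTop = nTop)
  callsDown <- rankTopBins(res, "downstream", exclude = rankExclude,
                           nTop = nTop)
  if (!is.null(ssb)) {
    callsUp <- classifyBreakBins(callsUp, ssb, nativeProf)
    callsDown <- classifyBreakBins(callsDown, ssb, nativeProf)
  }
  stretches <- motifs <- NULL
  if (!is.na(genomeSequence(genome))) {
    stretches <- findGCStretches(genome)
    motifs <- findG4Motifs(genome)
    callsUp <- annotateHotspots(callsUp, stretches, motifs, L, flank = flank)
    callsDown <- annotateHotspots(callsDown, stretches, motifs, L,
                                  flank = flank)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    nb <- nBins(nativeProf)
    iv <- .binInterval(seq_len(nb), binWidth, L)
    profTab <- data.frame(bin = seq_len(nb), bin_start = iv[, "start"],
                          bin_end = iv[, "end"],
                          native_upstream = nativeProf@upstream,
                          native_downstream = nativeProf@downstream)
    if (!is.null(s1Prof)) {
      profTab$s1_upstream <- s1Prof@upstream
      profTab$s1_downstream <- s1Prof@downstream
      profTab$ssb_upstream <- ssb@upstream
      profTab$ssb_downstream <- ssb@downstream
    }
    .writeReport(profTab, file.path(outDir, "profile.tsv"),
                 meta = list(bin_width = binWidth))
    .writeReport(rbind(callsUp, callsDown),
                 file.path(outDir, "hotspots.tsv"),
                 meta = list(ranked_on = rankOn, n_top = nTop,
                             excluded = paste(excludeLabels, collapse = ",")))
    if (!is.null(ssb))
      .writeReport(data.frame(clamped_upstream = ssb@clampedUpstream,
                              clamped_downstream = ssb@clampedDownstream),
                   file.path(outDir, "ssb_diagnostics.tsv"))
  }
  invisible(list(native = nativeProf, s1 = s1Prof, ssb = ssb,
                 residual = res, nativeResidual = nativeRes,
                 callsUpstream = callsUp, callsDownstream = callsDown,
                 stretches = stretches, motifs = motifs))
}

#' Fit decay kinetics for labeled series in a TSV
#'
#' Reads a time-series table (`time_h`, `signal`, `label`; `#` comments
#' allowed), fits an exponential decay per label, optionally decomposes
#' each apparent rate into degradation plus dilution, and writes
#' `decay_fits.tsv`.
#'
#' @param seriesPath TSV path or a data.frame.
#' @param outDir output directory, or `NULL` to skip writing.
#' @param doublingTime culture doubling time in hours for the dilution
#'   decomposition, or `NULL` to skip it.
#' @return invisibly, the fit report `data.frame`.
#' @export
runKinetics <- function(seriesPath, outDir = NULL, doublingTime = NULL) {
  series <- if (is.character(seriesPath))
    utils::read.delim(seriesPath, comment.char = "#",
                      stringsAsFactors = FALSE) else seriesPath
  if (!all(c("time_h", "signal") %in% names(series)))
    stop("series table needs columns time_h, signal", call. = FALSE)
  if (!nrow(series)) stop("empty series table", call. = FALSE)
  if (is.null(series$label)) series$label <- "series"
  rows <- lapply(split(series, series$label), function(s) {
    s <- s[order(s$time_h), ]
    fit <- fitExponential(s$time_h, s$signal, label = s$label[1])
    row <- data.frame(label = s$label[1], n = fit@n, k_per_h = fit@k,
                      half_life_h = fit@halfLife, rss = fit@rss)
    if (!is.null(doublingTime)) {
      dec <- decomposeDilution(fit, doublingTime)
      row$degradation_half_life_h <- dec$degradationHalfLife
      row$dilution_dominated <- dec$dilutionDominated
    }
    row
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeReport(report, file.path(outDir, "decay_fits.tsv"),
                 meta = if (is.null(doublingTime)) list() else
                   list(doubling_time_h = doublingTime))
  }
  invisible(report)
}
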