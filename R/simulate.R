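## Generative model for fragment libraries from a population of circular
## genomes carrying strand breaks. The chain mirrors the wet-lab protocol:
## breaks accumulate on circles; optional S1 nuclease converts nicks (SSBs)
## on either strand into DSBs; a single-cutter restriction enzyme
## linearizes; DSB positions partition each circle into linear fragments;
## bead size selection removes short fragments; trace nuclear fragments are
## appended. A DSB at position p separates p from p+1: the left fragment's
## downstream end is p, the right fragment's upstream end is p+1.

#' Simulation configuration for fragment-library generation
#'
#' Bundles and validates all parameters of the generative model.
#'
#' Randomness is governed by the single integer `seed`; the draw order is
#' fixed: per molecule (hotspot firing, heavy-strand background nick count
#' and positions, light-strand ditto), then per-molecule restriction-cut
#' Bernoulli draws, then the nuclear fragment count and lengths.
#'
#' @param genome a [CircularGenome-class] (sequence optional).
#' @param hotspots `data.frame(position, kind, rate)` of planted break
#'   hotspots; `kind` one of `"nick_heavy"`, `"nick_light"`, `"dsb"`;
#'   `rate` the per-molecule firing probability in `[0, 1]`.
#' @param backgroundNickRate per-base, per-strand nick probability (nick
#'   counts per strand are Poisson with mean `L * rate`, positions
#'   uniform).
#' @param nickToDsbDistance opposing-strand nicks within this circular
#'   distance (bp) collapse into one DSB at the heavy-strand nick position,
#'   modelling spontaneous DSB formation from clustered SSBs.
#' @param eagIPosition restriction cut position of the single-cutter used
#'   for linearization (default 2567, inside the 2550-2585 window whose
#'   ends are excluded downstream as artifacts).
#' @param eagIEfficiency per-molecule probability that the restriction cut
#'   occurs.
#' @param s1Treated whether [sampleLibrary()] applies [s1Treat()] before
#'   linearization.
#' @param nMolecules number of circular molecules.
#' @param sizeMin size-selection threshold in bp; fragments with
#'   `length >= sizeMin` are retained (default 3000, i.e. "remove
#'   fragments < 3 kb").
#' @param nuclearFraction expected proportion of nuclear background
#'   records in the output library, in `[0, 1)`.
#' @param nuclearMeanLog,nuclearSdLog log-normal parameters of the nuclear
#'   fragment length law (default median 8 kb, sigma_log 0.5), truncated
#'   at `sizeMin`.
#' @param seed integer seed for all randomness.
#' @return a validated `SimulationConfig` list.
#' @export
simulationConfig <- function(genome, hotspots = NULL,
                             backgroundNickRate = 0,
                             nickToDsbDistance = 10L,
                             eagIPosition = 2567L, eagIEfficiency = 0.9,
                             s1Treated = FALSE, nMolecules = 1000L,
                             sizeMin = 3000L, nuclearFraction = 0,
                             nuclearMeanLog = log(8000),
                             nuclearSdLog = 0.5, seed = 1L) {
  stopifnot(is(genome, "CircularGenome"))
  L <- genomeLength(genome)
  if (is.null(hotspots))
    hotspots <- data.frame(position = integer(0), kind = character(0),
                           rate = numeric(0))
  if (!all(c("position", "kind", "rate") %in% names(hotspots)))
    stop("hotspots must have columns position, kind, rate", call. = FALSE)
  if (!all(hotspots$kind %in% c("nick_heavy", "nick_light", "dsb")))
    stop("hotspot kind must be nick_heavy, nick_light or dsb", call. = FALSE)
  if (any(hotspots$rate < 0 | hotspots$rate > 1))
    stop("hotspot rates must lie in [0, 1]", call. = FALSE)
  if (nrow(hotspots)) .checkPositions(hotspots$position, L, "hotspot position")
  if (backgroundNickRate < 0 || backgroundNickRate > 1)
    stop("backgroundNickRate must lie in [0, 1]", call. = FALSE)
  if (eagIEfficiency < 0 || eagIEfficiency > 1)
    stop("eagIEfficiency must lie in [0, 1]", call. = FALSE)
  .checkPositions(eagIPosition, L, "eagIPosition")
  if (nMolecules < 1L) stop("nMolecules must be positive", call. = FALSE)
  if (sizeMin < 0L) stop("sizeMin must be >= 0", call. = FALSE)
  if (nuclearFraction < 0 || nuclearFraction >= 1)
    stop("nuclearFraction must lie in [0, 1)", call. = FALSE)
  structure(list(
    genome = genome, hotspots = hotspots,
    backgroundNickRate = backgroundNickRate,
    nickToDsbDistance = as.integer(nickToDsbDistance),
    eagIPosition = as.integer(eagIPosition),
    eagIEfficiency = eagIEfficiency, s1Treated = isTRUE(s1Treated),
    nMolecules = as.integer(nMolecules), sizeMin = as.integer(sizeMin),
    nuclearFraction = nuclearFraction, nuclearMeanLog = nuclearMeanLog,
    nuclearSdLog = nuclearSdLog, seed = as.integer(seed)),
    class = "SimulationConfig")
}

## Collapse opposing-strand nicks closer than d bp into a DSB placed at
## the heavy-strand nick; each light nick pairs with at most one heavy
## nick (nearest first, scanning heavy nicks in coordinate order).
.convertOpposingNicks <- function(nh, nl, dsb, d, L) {
  if (length(nh) && length(nl) && d > 0L) {
    keepH <- rep(TRUE, length(nh)); keepL <- rep(TRUE, length(nl))
    for (i in seq_along(nh)) {
      cand <- which(keepL)
      if (!length(cand)) break
      dd <- circDistance(rep(nh[i], length(cand)), nl[cand], L)
      j <- cand[which.min(dd)]
      if (min(dd) <= d) {
        keepH[i] <- FALSE; keepL[j] <- FALSE
        dsb <- c(dsb, nh[i])
      }
    }
    nh <- nh[keepH]; nl <- nl[keepL]
  }
  list(nicksHeavy = sort(unique(nh)), nicksLight = sort(unique(nl)),
       dsbs = sort(unique(dsb)))
}

#' Simulate a population of broken circular molecules
#'
#' For each molecule, every hotspot fires independently at its rate;
#' background nicks are drawn per strand as a Poisson process; DSB
#' hotspots deposit a DSB directly; opposing-strand nicks within
#' `nickToDsbDistance` bp collapse into one DSB at the heavy-strand nick
#' position.
#'
#' @param config a [simulationConfig()].
#' @param seed seed applied before drawing (default `config$seed`); pass
#'   `NULL` to continue from the current RNG state (used internally by
#'   [sampleLibrary()]).
#' @return list of molecule states, each
#'   `list(nicksHeavy, nicksLight, dsbs)` of sorted, duplicate-free
#'   positions.
#' @export
simulateMolecules <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  L <- genomeLength(config$genome)
  h <- config$hotspots
  lam <- L * config$backgroundNickRate
  lapply(seq_len(config$nMolecules), function(i) {
    fired <- if (nrow(h)) stats::runif(nrow(h)) < h$rate else logical(0)
    nh <- h$position[fired & h$kind == "nick_heavy"]
    nl <- h$position[fired & h$kind == "nick_light"]
    db <- h$position[fired & h$kind == "dsb"]
    if (lam > 0) {
      kH <- stats::rpois(1L, lam)
      if (kH) nh <- c(nh, sample.int(L, kH, replace = TRUE))
      kL <- stats::rpois(1L, lam)
      if (kL) nl <- c(nl, sample.int(L, kL, replace = TRUE))
    }
    .convertOpposingNicks(unique(nh), unique(nl), unique(db),
                          config$nickToDsbDistance, L)
  })
}

#' S1 nuclease treatment of a molecule
#'
#' S1 nuclease converts single-strand breaks (nicks and gaps) into
#' double-strand breaks: the returned molecule's DSB list is the union of
#' its DSBs and the nicks of both strands, and its nick lists are empty.
#' Idempotent.
#'
#' @param m a molecule state from [simulateMolecules()].
#' @return the treated molecule state.
#' @export
s1Treat <- function(m) {
  list(nicksHeavy = integer(0), nicksLight = integer(0),
       dsbs = sort(unique(c(m$dsbs, m$nicksHeavy, m$nicksLight))))
}

#' Linearize a molecule and fragment it at DSB positions
#'
#' With probability `eagIEfficiency` the restriction cut is added at
#' `eagIPosition`; all DSB positions (plus the cut) then partition the
#' circle into clockwise arcs, one fragment per arc. A molecule with no
#' cut stays circular and yields no fragment; a single cut yields one
#' full-length linear fragment. A cut at `p` puts `p` at the downstream
#' end of one fragment and `p + 1` (mod L) at the upstream end of the
#' next.
#'
#' @param m molecule state.
#' @param config a [simulationConfig()].
#' @param eagICut override the Bernoulli draw: `TRUE`/`FALSE` forces the
#'   cut on/off; `NULL` (default) draws with `config$eagIEfficiency`.
#' @return `data.frame(compartment, upstream_end, downstream_end, length,
#'   origin_spanning)`, zero rows when the molecule has no cut.
#' @export
linearizeAndFragment <- function(m, config, eagICut = NULL) {
  L <- genomeLength(config$genome)
  cuts <- m$dsbs
  if (is.null(eagICut)) eagICut <- stats::runif(1L) < config$eagIEfficiency
  if (eagICut) cuts <- c(cuts, config$eagIPosition)
  cuts <- sort(unique(as.integer(cuts)))
  if (!length(cuts)) return(.emptyFragmentTable())
  up <- rotateCoordinates(cuts, 1L, L)          # cut + 1, wrapping
  down <- c(cuts[-1L], cuts[1L])
  len <- ((down - up) %% L) + 1L
  data.frame(compartment = "mito", upstream_end = up, downstream_end = down,
             length = as.integer(len), origin_spanning = up > down,
             stringsAsFactors = FALSE)
}

.emptyFragmentTable <- function() {
  data.frame(compartment = character(0), upstream_end = integer(0),
             downstream_end = integer(0), length = integer(0),
             origin_spanning = logical(0), stringsAsFactors = FALSE)
}

#' Size-select fragments
#'
#' Retains fragments with `length >= sizeMin` (the bead cleanup removes
#' fragments below the threshold; a fragment of exactly the threshold
#' length is kept). Order is stable.
#'
#' @param frags fragment table.
#' @param sizeMin threshold in bp.
#' @return filtered fragment table.
#' @export
sizeSelect <- function(frags, sizeMin) {
  if (is.null(frags) || !nrow(frags)) return(.emptyFragmentTable())
  out <- frags[frags$length >= sizeMin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## linearize + size-select the molecule list, then append nuclear
## background fragments; assumes the RNG state is already positioned.
.assembleLibrary <- function(mols, config) {
  eagDraws <- stats::runif(length(mols)) < config$eagIEfficiency
  parts <- lapply(seq_along(mols), function(i)
    linearizeAndFragment(mols[[i]], config, eagICut = eagDraws[i]))
  frags <- do.call(rbind, parts)
  frags <- sizeSelect(frags, config$sizeMin)
  f <- config$nuclearFraction
  if (f > 0 && nrow(frags)) {
    nNuc <- stats::rpois(1L, nrow(frags) * f / (1 - f))
    if (nNuc > 0) {
      lens <- integer(0)
      while (length(lens) < nNuc) {  # rejection sampling under truncation
        draw <- stats::rlnorm(2L * (nNuc - length(lens)) + 8L,
                              config$nuclearMeanLog, config$nuclearSdLog)
        lens <- c(lens, as.integer(round(draw[draw >= config$sizeMin])))
      }
      lens <- lens[seq_len(nNuc)]
      nuc <- data.frame(compartment = "nuclear", upstream_end = NA_integer_,
                        downstream_end = NA_integer_, length = lens,
                        origin_spanning = NA, stringsAsFactors = FALSE)
      frags <- rbind(frags, nuc)
    }
  }
  rownames(frags) <- NULL
  frags
}

#' Generate a complete fragment library
#'
#' Runs the full generative chain: simulate molecules, optionally apply S1
#' treatment, linearize and fragment, size-select, and append nuclear
#' background fragments with log-normal lengths truncated at `sizeMin`, so
#' that nuclear records form an expected `nuclearFraction` of the output.
#' Deterministic under `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return fragment table (`data.frame(compartment, upstream_end,
#'   downstream_end, length, origin_spanning)`).
#' @export
sampleLibrary <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  mols <- simulateMolecules(config, seed = NULL)
  if (config$s1Treated) mols <- lapply(mols, s1Treat)
  .assembleLibrary(mols, config)
}

#' Write / read a fragment table as TSV
#'
#' The TSV has a header line (`compartment`, `upstream_end`,
#' `downstream_end`, `length`, `origin_spanning`) preceded by `#` comment
#' lines recording provenance (tool version, seed, parameter digest).
#'
#' @param frags fragment table.
#' @param path output file.
#' @param meta named list written as `# key=value` comment lines.
#' @return `path`, invisibly.
#' @export
writeFragmentTable <- function(frags, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mtbreaks %s",
                     as.character(utils::packageVersion("mtbreaks"))), con)
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]])), con)
  utils::write.table(frags, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentTable
#' @export
readFragmentTable <- function(path) {
  frags <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  need <- c("compartment", "upstream_end", "downstream_end", "length")
  if (!all(need %in% names(frags)))
    stop("fragment table is missing required columns: ",
         paste(setdiff(need, names(frags)), collapse = ", "), call. = FALSE)
  if (is.null(frags$origin_spanning))
    frags$origin_spanning <- !is.na(frags$upstream_end) &
      frags$upstream_end > frags$downstream_end
  frags
}

#' Read fragments from a BED file
#'
#' Converts 0-based half-open BED records to the package's 1-based
#' inclusive convention: `upstream_end = chromStart + 1`,
#' `downstream_end = chromEnd`. The BED name column (4th), when present,
#' is taken as the compartment (`mito`/`nuclear`); otherwise all records
#' are mito. BED cannot represent origin-spanning fragments; use the
#' fragment TSV for those.
#'
#' @param path BED file.
#' @param L genome length used to compute fragment lengths for mito
#'   records.
#' @return fragment table as in [sampleLibrary()].
#' @export
readFragmentBed <- function(path, L) {
  bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  comp <- if (ncol(bed) >= 4L) bed[[4L]] else "mito"
  up <- as.integer(bed[[2L]]) + 1L
  down <- as.integer(bed[[3L]])
  if (any(up > down))
    stop("BED records must have chromStart < chromEnd", call. = FALSE)
  data.frame(compartment = comp, upstream_end = up, downstream_end = down,
             length = down - up + 1L, origin_spanning = FALSE,
             stringsAsFactors = FALSE)
}
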