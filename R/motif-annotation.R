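## Sequence context of called hotspots: maximal GC runs and putative
## G-quadruplex-forming motifs (four tracts of >= 3 G separated by loops
## of 1-7 nt, the classic Quadparser rule) on both strands, with circular
## handling via scanning the doubled sequence. A rotation-permutation
## test quantifies hotspot/motif co-localization.

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Find maximal GC stretches on a circular genome
#'
#' Maximal runs of `{G, C}` of at least `minRun` bases, strand-agnostic,
#' including runs spanning the coordinate origin (reported with
#' `start > end`). Runs are non-overlapping by maximality.
#'
#' @param genome a [CircularGenome-class] with sequence.
#' @param minRun minimal run length (default 6).
#' @return `data.frame(start, end, length, sequence)`.
#' @export
findGCStretches <- function(genome, minRun = 6L) {
  stopifnot(is(genome, "CircularGenome"))
  if (minRun < 1L) stop("minRun must be >= 1", call. = FALSE)
  s <- genomeSequence(genome)
  if (is.na(s)) stop("genome sequence required for motif scanning",
                     call. = FALSE)
  L <- genomeLength(genome)
  gc <- strsplit(s, "")[[1]] %in% c("G", "C")
  r <- rle(gc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  st <- starts[keep]; en <- ends[keep]
  if (length(st) && all(gc)) {            # fully-GC circle: one run
    st <- 1L; en <- L
  } else if (length(st) > 1L && gc[1L] && gc[L]) {
    # merge the run touching position L with the run starting at 1
    st[1L] <- st[length(st)]
    st <- st[-length(st)]; en <- en[-length(en)]
  }
  len <- ifelse(st <= en, en - st + 1L, L - st + 1L + en)
  ok <- len >= minRun
  st <- st[ok]; en <- en[ok]; len <- len[ok]
  if (!length(st))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  dd <- paste0(s, s)
  seqs <- substring(dd, st, ifelse(st <= en, en, en + L))
  data.frame(start = st, end = en, length = as.integer(len),
             sequence = seqs, stringsAsFactors = FALSE)
}

## leftmost non-overlapping matches of pat on the doubled sequence,
## keeping matches that start in the first copy; end coordinates wrap
.scanCircular <- function(s, pat, L) {
  m <- gregexpr(pat, paste0(s, s), perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0),
                                     pattern = character(0)))
  len <- attr(m, "match.length")
  keep <- m <= L & len <= L
  st <- as.integer(m[keep]); len <- len[keep]
  endRaw <- st + len - 1L
  data.frame(start = st, end = as.integer(((endRaw - 1L) %% L) + 1L),
             pattern = substring(paste0(s, s), st, endRaw),
             stringsAsFactors = FALSE)
}

#' Find putative G-quadruplex motifs on both strands
#'
#' Matches `G{3,}(N{1,7}G{3,}){3}` (four tracts of at least three
#' guanines separated by 1-7 nt loops) on the heavy strand and on the
#' reverse complement; light-strand matches are reported in heavy-strand
#' coordinates. Origin-spanning matches are found by scanning the doubled
#' sequence; matching is leftmost, shortest (lazy quantifiers, so a
#' circular match never exceeds one circumference) and non-overlapping
#' per strand.
#'
#' @param genome a [CircularGenome-class] with sequence.
#' @param minTract minimal G-tract length (default 3).
#' @param maxLoop maximal loop length (default 7).
#' @return `data.frame(start, end, strand, pattern)` with `strand` in
#'   `{heavy, light}`.
#' @export
findG4Motifs <- function(genome, minTract = 3L, maxLoop = 7L) {
  stopifnot(is(genome, "CircularGenome"))
  s <- genomeSequence(genome)
  if (is.na(s)) stop("genome sequence required for motif scanning",
                     call. = FALSE)
  L <- genomeLength(genome)
  pat <- sprintf("G{%d,}?(?:[ACGTN]{1,%d}?G{%d,}?){3}",
                 minTract, maxLoop, minTract)
  heavy <- .scanCircular(s, pat, L)
  rcHits <- .scanCircular(.revcomp(s), pat, L)
  ## reverse-complement position q maps to heavy-strand position L-q+1;
  ## the match [s,e] on the light strand occupies heavy arc [map(e), map(s)]
  mapPos <- function(q) L - as.integer(((q - 1L) %% L) + 1L) + 1L
  light <- data.frame(start = mapPos(rcHits$start + nchar(rcHits$pattern) - 1L),
                      end = mapPos(rcHits$start),
                      pattern = rcHits$pattern, stringsAsFactors = FALSE)
  out <- rbind(cbind(heavy, strand = rep("heavy", nrow(heavy))),
               cbind(light, strand = rep("light", nrow(light))))
  rownames(out) <- NULL
  out[c("start", "end", "strand", "pattern")]
}

#' Annotate hotspot calls with nearby motifs
#'
#' Sets per-call boolean flags `gc_within_flank` and `g4_within_flank`:
#' `TRUE` when any GC stretch (resp. G4 motif) lies within `flank` bp of
#' the call's bin interval by circular arc distance (overlap counts as
#' distance 0). Idempotent.
#'
#' @param calls output of [rankTopBins()] (needs `bin_start`, `bin_end`).
#' @param stretches output of [findGCStretches()] (or `NULL`).
#' @param motifs output of [findG4Motifs()] (or `NULL`).
#' @param L genome length.
#' @param flank flank distance in bp (default 0: require overlap).
#' @return `calls` with the two flag columns added/overwritten.
#' @export
annotateHotspots <- function(calls, stretches, motifs, L, flank = 0L) {
  near <- function(tab) {
    if (is.null(tab) || !nrow(tab)) return(rep(FALSE, nrow(calls)))
    vapply(seq_len(nrow(calls)), function(i)
      any(.circIntervalDistance(calls$bin_start[i], calls$bin_end[i],
                                tab$start, tab$end, L) <= flank),
      logical(1))
  }
  calls$gc_within_flank <- near(stretches)
  calls$g4_within_flank <- near(motifs)
  calls
}

#' Rotation-permutation test of hotspot/motif association
#'
#' Observed statistic: number of calls with a motif within `flank` bp.
#' Null: the motif set is rotated by uniform random circular offsets
#' (preserving motif clustering) and the overlap count recomputed.
#' `p = (1 + #\{null >= observed\}) / (1 + nRotations)` (add-one rule, so
#' p is never 0).
#'
#' @param calls output of [rankTopBins()].
#' @param motifs motif table with `start`, `end` columns.
#' @param L genome length.
#' @param nRotations number of random rotations (default 999).
#' @param flank flank distance in bp.
#' @param seed integer seed.
#' @return `list(pValue, observed, expectedNull, nRotations)`.
#' @export
rotationAssociationTest <- function(calls, motifs, L, nRotations = 999L,
                                    flank = 0L, seed = 1L) {
  if (nRotations < 1L) stop("nRotations must be >= 1", call. = FALSE)
  if (!nrow(calls) || !nrow(motifs))
    stop("need at least one call and one motif", call. = FALSE)
  overlapCount <- function(tab)
    sum(vapply(seq_len(nrow(calls)), function(i)
      any(.circIntervalDistance(calls$bin_start[i], calls$bin_end[i],
                                tab$start, tab$end, L) <= flank),
      logical(1)))
  observed <- overlapCount(motifs)
  set.seed(seed)
  offsets <- sample.int(L, nRotations, replace = TRUE)
  null <- vapply(offsets, function(off) {
    rot <- motifs
    rot$start <- rotateCoordinates(motifs$start, off, L)
    rot$end <- rotateCoordinates(motifs$end, off, L)
    overlapCount(rot)
  }, numeric(1))
  list(pValue = (1 + sum(null >= observed)) / (1 + nRotations),
       observed = observed, expectedNull = mean(null),
       nRotations = as.integer(nRotations))
}
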