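## Circular-coordinate arithmetic. Everything downstream (binning, hotspot
## ranking, motif flanks) reduces to these three primitives plus the
## interval-overlap helpers at the bottom.

.checkPositions <- function(p, L, what = "position") {
  if (any(is.na(p)) || any(p < 1L) || any(p > L))
    stop(sprintf("%s out of range [1, %d]", what, L), call. = FALSE)
  invisible(p)
}

#' Minimal arc distance between two positions on a circle
#'
#' @param a,b 1-based positions (vectorized).
#' @param L circle length in bp.
#' @return minimal arc distance `min((a-b) mod L, (b-a) mod L)`;
#'   symmetric, at most `L/2`.
#' @examples
#' circDistance(16569, 1, 16569) # wraparound neighbours
#' @export
circDistance <- function(a, b, L) {
  .checkPositions(a, L); .checkPositions(b, L)
  d <- (a - b) %% L
  pmin(d, L - d)
}

#' Circular interval membership
#'
#' Tests whether positions lie on the clockwise arc from `start` to `end`
#' inclusive. Intervals with `start > end` span the coordinate origin
#' (the human mtDNA D-loop, 16030-570, contains position 16300 and
#' position 5, but not 571).
#'
#' @param p positions to test (vectorized).
#' @param start,end interval endpoints, 1-based inclusive.
#' @param L circle length.
#' @return logical vector.
#' @export
intervalContains <- function(p, start, end, L) {
  .checkPositions(p, L)
  .checkPositions(start, L, "interval start")
  .checkPositions(end, L, "interval end")
  if (start <= end) p >= start & p <= end else p >= start | p <= end
}

#' Rotate circular coordinates
#'
#' Shifts positions clockwise by `shift` bp with wraparound:
#' `((p - 1 + shift) mod L) + 1`. Bijective for a fixed shift; the inverse
#' shift restores the input. Used by the rotation-equivariance checks and
#' the motif rotation-permutation test.
#'
#' @param p positions (vectorized).
#' @param shift signed shift in bp.
#' @param L circle length.
#' @return rotated positions in `[1, L]`.
#' @export
rotateCoordinates <- function(p, shift, L) {
  .checkPositions(p, L)
  as.integer(((p - 1L + shift) %% L) + 1L)
}

#' Read a circular reference genome from FASTA
#'
#' Reads the first record of a FASTA file as a [CircularGenome-class].
#'
#' @param path FASTA file.
#' @param name genome name; defaults to the FASTA record name.
#' @param regions optional region table passed to [CircularGenome()].
#' @return a [CircularGenome-class].
#' @export
readGenomeFasta <- function(path, name = NULL, regions = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (length(ss) > 1L)
    warning("multiple FASTA records; using the first (multi-contig genomes unsupported)")
  CircularGenome(name = if (is.null(name)) names(ss)[1] else name,
                 sequence = as.character(ss[[1]]), regions = regions)
}

#' Read a circular region annotation table
#'
#' Reads a TSV with a header line and columns `label`, `start`, `end`
#' (1-based inclusive circular coordinates; `start > end` spans the
#' origin). Lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return `data.frame(label, start, end)`.
#' @export
readRegionTable <- function(path) {
  rg <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("label", "start", "end")
  if (!all(need %in% names(rg)))
    stop("region table must have columns label, start, end", call. = FALSE)
  rg$start <- as.integer(rg$start)
  rg$end <- as.integer(rg$end)
  rg[need]
}

## Circular interval-interval predicates, used by hotspot ranking
## (exclusion regions) and motif annotation (flank distance).

.containsV <- function(p, start, end, L)
  (start <= end & p >= start & p <= end) |
  (start > end & (p >= start | p <= end))

.circIntervalsOverlap <- function(as, ae, bs, be, L) {
  .containsV(bs, as, ae, L) | .containsV(be, as, ae, L) |
    .containsV(as, bs, be, L) | .containsV(ae, bs, be, L)
}

## Minimal gap in bp between two circular arcs; 0 when they overlap.
.circIntervalDistance <- function(as, ae, bs, be, L) {
  ifelse(.circIntervalsOverlap(as, ae, bs, be, L), 0L,
         pmin((bs - ae) %% L, (as - be) %% L))
}
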