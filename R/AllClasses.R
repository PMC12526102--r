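#' @import methods
NULL

#' CircularGenome: a circular reference genome
#'
#' Holds a circular genome of length `L` with optional nucleotide sequence
#' and a set of named circular regions. All coordinates in the package are
#' 1-based inclusive on this circle; an interval with `start > end` spans
#' the coordinate origin (e.g. the human mtDNA D-loop, 16030-570).
#'
#' The sequence is optional: end profiling and break calling only need the
#' genome length, while motif scanning and sequence output by the simulator
#' require the sequence.
#'
#' @slot name genome name.
#' @slot sequence nucleotide sequence as a single uppercase string over
#'   `A,C,G,T,N`, or `character(0)` when only the length is known.
#' @slot genomeLength circle length in bp.
#' @slot regions `data.frame` with columns `label`, `start`, `end`
#'   (1-based inclusive, circular; `start > end` spans the origin).
#'
#' @export
setClass("CircularGenome",
  representation(name = "character", sequence = "character",
                 genomeLength = "integer", regions = "data.frame"))

setValidity("CircularGenome", function(object) {
  L <- object@genomeLength
  if (length(L) != 1L || is.na(L) || L < 1L)
    return("genomeLength must be a single positive integer")
  if (length(object@sequence) > 1L)
    return("sequence must be a single string or empty")
  if (length(object@sequence) == 1L) {
    if (nchar(object@sequence) != L)
      return(sprintf("sequence length (%d) != genomeLength (%d)",
                     nchar(object@sequence), L))
    if (grepl("[^ACGTN]", object@sequence))
      return("sequence alphabet must be within {A,C,G,T,N}")
  }
  rg <- object@regions
  if (nrow(rg)) {
    if (!all(c("label", "start", "end") %in% names(rg)))
      return("regions must have columns label, start, end")
    if (anyDuplicated(rg$label))
      return("region labels must be unique")
    if (any(rg$start < 1L | rg$start > L | rg$end < 1L | rg$end > L))
      return("region coordinates must lie in [1, genomeLength]")
  }
  TRUE
})

#' Construct a CircularGenome
#'
#' @param name genome name.
#' @param length circle length in bp; defaults to the human mtDNA length
#'   16,569 bp, or to `nchar(sequence)` when a sequence is supplied.
#' @param sequence optional nucleotide sequence (a string or a
#'   [Biostrings::DNAString]); converted to uppercase.
#' @param regions optional `data.frame(label, start, end)` of circular
#'   regions; defaults to [humanMtRegions()] when `length` is 16,569 and
#'   no regions are given, else to an empty table.
#'
#' @return a [CircularGenome-class] object.
#' @examples
#' g <- CircularGenome("toy", sequence = "ATGCCGGCAT")
#' genomeLength(g)
#' @export
CircularGenome <- function(name = "circular_genome", length = NULL,
                           sequence = NULL, regions = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (is.null(length)) length <- nchar(sequence)
  } else {
    sequence <- character(0)
    if (is.null(length)) length <- 16569L
  }
  length <- as.integer(length)
  if (is.null(regions)) {
    regions <- if (length == 16569L) humanMtRegions() else
      data.frame(label = character(0), start = integer(0), end = integer(0))
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  new("CircularGenome", name = name, sequence = sequence,
      genomeLength = length, regions = regions)
}

#' Standard human mtDNA region annotations
#'
#' Circular regions of the human mitochondrial genome used throughout the
#' package: the D-loop control region (spanning the coordinate origin), the
#' replication origins oriH and oriL, the termination-associated sequence
#' (TAS), and the exclusion window around the EagI linearization site whose
#' fragment ends are library artifacts.
#'
#' @return `data.frame(label, start, end)`, 1-based inclusive circular
#'   coordinates (`start > end` spans the origin).
#' @export
humanMtRegions <- function() {
  data.frame(
    label = c("D-loop", "oriH", "oriL", "TAS", "EagI_exclusion"),
    start = c(16030L, 110L, 5770L, 16157L, 2550L),
    end   = c(570L, 441L, 5820L, 16172L, 2585L))
}

#' @describeIn CircularGenome-class genome length in bp.
#' @param x,object a `CircularGenome`.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname CircularGenome-class
#' @export
setMethod("genomeLength", "CircularGenome", function(x) x@genomeLength)

#' @describeIn CircularGenome-class genome sequence (`NA` if absent).
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname CircularGenome-class
#' @export
setMethod("genomeSequence", "CircularGenome", function(x)
  if (length(x@sequence)) x@sequence else NA_character_)

#' @describeIn CircularGenome-class region annotation table.
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname CircularGenome-class
#' @export
setMethod("regions", "CircularGenome", function(x) x@regions)

setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %d bp (%s sequence), %d region(s)\n",
              object@name, object@genomeLength,
              if (length(object@sequence)) "with" else "no",
              nrow(object@regions)))
  if (nrow(object@regions))
    cat(" ", paste(object@regions$label, collapse = ", "), "\n")
})

#' BinnedEndProfile: binned fragment-end frequencies for one library
#'
#' Per-bin counts (or depth-normalized frequencies) of upstream and
#' downstream fragment ends along a circular genome. Bin `k` (1-based)
#' covers positions `[(k-1)*binWidth + 1, k*binWidth]` clipped at the
#' genome length, so the final bin may be short.
#'
#' @slot binWidth bin width in bp.
#' @slot genomeLength circle length in bp.
#' @slot upstream,downstream per-bin values, length `ceiling(L/binWidth)`.
#' @slot normalized `"raw_counts"` or `"per_depth"`.
#' @slot depth mean sequencing depth used for normalization (`NA` for raw).
#' @slot meta list of library metadata (condition label, `s1Treated` flag,
#'   excluded-end count).
#'
#' @export
setClass("BinnedEndProfile",
  representation(binWidth = "integer", genomeLength = "integer",
                 upstream = "numeric", downstream = "numeric",
                 normalized = "character", depth = "numeric", meta = "list"))

setValidity("BinnedEndProfile", function(object) {
  nb <- ceiling(object@genomeLength / object@binWidth)
  if (length(object@upstream) != nb || length(object@downstream) != nb)
    return(sprintf("profile vectors must have %d bins", nb))
  if (!object@normalized %in% c("raw_counts", "per_depth"))
    return("normalized must be 'raw_counts' or 'per_depth'")
  if (any(object@upstream < 0) || any(object@downstream < 0))
    return("end frequencies must be non-negative")
  if (object@normalized == "raw_counts" &&
      (any(object@upstream != floor(object@upstream)) ||
       any(object@downstream != floor(object@downstream))))
    return("raw counts must be integers")
  TRUE
})

#' @describeIn BinnedEndProfile-class number of bins.
#' @param x,object a profile.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname BinnedEndProfile-class
#' @export
setMethod("nBins", "BinnedEndProfile",
          function(x) as.integer(ceiling(x@genomeLength / x@binWidth)))

#' @describeIn BinnedEndProfile-class per-bin upstream-end values.
#' @export
setGeneric("upstreamValues", function(x) standardGeneric("upstreamValues"))

#' @rdname BinnedEndProfile-class
#' @export
setMethod("upstreamValues", "BinnedEndProfile", function(x) x@upstream)

#' @describeIn BinnedEndProfile-class per-bin downstream-end values.
#' @export
setGeneric("downstreamValues", function(x) standardGeneric("downstreamValues"))

#' @rdname BinnedEndProfile-class
#' @export
setMethod("downstreamValues", "BinnedEndProfile", function(x) x@downstream)

#' @describeIn BinnedEndProfile-class bin width in bp.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedEndProfile-class
#' @export
setMethod("binWidth", "BinnedEndProfile", function(x) x@binWidth)

setMethod("show", "BinnedEndProfile", function(object) {
  cat(sprintf(
    "BinnedEndProfile: %d bins of %d bp on a %d bp circle (%s)\n",
    nBins(object), object@binWidth, object@genomeLength, object@normalized))
  cat(sprintf("  upstream ends: total %.4g; downstream ends: total %.4g\n",
              sum(object@upstream), sum(object@downstream)))
})

#' SSBProfile: differential single-strand-break frequencies
#'
#' A [BinnedEndProfile-class] whose values are the clamped per-bin
#' difference between an S1-treated and a native library
#' (`max(0, S1 - native)`), estimating single-strand-break end frequencies.
#' Bins where the raw difference was negative (sampling noise) are clamped
#' to zero and counted.
#'
#' @slot clampedUpstream,clampedDownstream number of clamped bins per end
#'   class.
#' @export
setClass("SSBProfile", contains = "BinnedEndProfile",
  representation(clampedUpstream = "integer", clampedDownstream = "integer"))

#' ResidualProfile: background-subtracted end-frequency residuals
#'
#' Per-bin residuals after subtracting a circular running-median background
#' from a [BinnedEndProfile-class]; the ranking substrate for hotspot
#' calling.
#'
#' @slot binWidth,genomeLength as in the source profile.
#' @slot upstream,downstream per-bin residuals (may be negative).
#' @slot windowHalfwidth background window half-width in bins.
#' @export
setClass("ResidualProfile",
  representation(binWidth = "integer", genomeLength = "integer",
                 upstream = "numeric", downstream = "numeric",
                 windowHalfwidth = "integer"))

setValidity("ResidualProfile", function(object) {
  nb <- ceiling(object@genomeLength / object@binWidth)
  if (length(object@upstream) != nb || length(object@downstream) != nb)
    return(sprintf("residual vectors must have %d bins", nb))
  if (!all(is.finite(object@upstream)) || !all(is.finite(object@downstream)))
    return("residuals must be finite")
  TRUE
})

#' @rdname ResidualProfile-class
#' @param x a `ResidualProfile`.
#' @export
setMethod("nBins", "ResidualProfile",
          function(x) as.integer(ceiling(x@genomeLength / x@binWidth)))

#' @rdname ResidualProfile-class
#' @export
setMethod("upstreamValues", "ResidualProfile", function(x) x@upstream)

#' @rdname ResidualProfile-class
#' @export
setMethod("downstreamValues", "ResidualProfile", function(x) x@downstream)

setMethod("show", "ResidualProfile", function(object) {
  cat(sprintf(
    "ResidualProfile: %d bins, running-median window half-width %d bins\n",
    nBins(object), object@windowHalfwidth))
})

#' DecayFit: fitted exponential decay
#'
#' Result of [fitExponential()]: log-linear (or nonlinear) least-squares
#' fit of `N0 * exp(-k * t)` to a decay series.
#'
#' @slot k decay rate per unit time (0 for a constant series).
#' @slot N0 fitted amplitude at `t = 0`.
#' @slot halfLife `log(2)/k` (Inf when `k <= 0`).
#' @slot rss residual sum of squares (on the log scale for the log-linear
#'   method).
#' @slot label series label.
#' @slot n number of points fitted.
#' @slot method `"loglinear"` or `"nls"`.
#' @export
setClass("DecayFit",
  representation(k = "numeric", N0 = "numeric", halfLife = "numeric",
                 rss = "numeric", label = "character", n = "integer",
                 method = "character"))

#' @describeIn DecayFit-class half-life `log(2)/k`.
#' @param x,object a fit object.
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname DecayFit-class
#' @export
setMethod("halfLife", "DecayFit", function(x) x@halfLife)

setMethod("show", "DecayFit", function(object) {
  cat(sprintf(
    "DecayFit%s: k = %.5g per unit time, half-life = %.4g, N0 = %.4g (n = %d, %s)\n",
    if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
    object@k, object@halfLife, object@N0, object@n, object@method))
})

#' ChapmanFit: fitted four-parameter Chapman qPCR curve
#'
#' Result of [chapmanFit()]: nonlinear least-squares fit of
#' `y = y0 + a * (1 - exp(-b*x))^c` to a qPCR amplification curve. The
#' quantification cycle Ct is the inflection point `ln(c)/b`, defined only
#' for shape `c > 1`.
#'
#' @slot y0 baseline fluorescence.
#' @slot a amplitude.
#' @slot b rate per cycle (> 0).
#' @slot c shape (dimensionless).
#' @slot ct inflection cycle `log(c)/b` (`NA` at the `c <= 1` boundary).
#' @slot rss residual sum of squares.
#' @slot converged whether the optimizer converged.
#' @slot cBoundary `TRUE` when the fitted shape is at or near the `c = 1`
#'   boundary, where the curve degenerates to a saturating exponential with
#'   no interior inflection.
#' @export
setClass("ChapmanFit",
  representation(y0 = "numeric", a = "numeric", b = "numeric", c = "numeric",
                 ct = "numeric", rss = "numeric", converged = "logical",
                 cBoundary = "logical"))

#' @describeIn ChapmanFit-class inflection-point quantification cycle.
#' @param x,object a `ChapmanFit`.
#' @export
setGeneric("inflectionCt", function(x) standardGeneric("inflectionCt"))

#' @rdname ChapmanFit-class
#' @export
setMethod("inflectionCt", "ChapmanFit", function(x) x@ct)

setMethod("show", "ChapmanFit", function(object) {
  cat(sprintf(
    "ChapmanFit: y0 = %.4g, a = %.4g, b = %.4g, c = %.4g; Ct = %.4f%s\n",
    object@y0, object@a, object@b, object@c, object@ct,
    if (object@cBoundary) " (c ~ 1 boundary: inflection undefined)" else ""))
})
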