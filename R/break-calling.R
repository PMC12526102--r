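## Hotspot calling. Native libraries report DSB ends only; S1-treated
## libraries report SSB + DSB ends, so the clamped per-bin difference
## (S1 - native) estimates the SSB component. Hotspots are ranked by the
## residual left after subtracting a circular running-median background,
## excluding bins that overlap regions dominated by replication
## intermediates (D-loop, oriL).

#' Differential single-strand-break profile
#'
#' Per bin, `SSB = max(0, S1 - native)` between two depth-normalized
#' profiles with identical binning: S1-treated ends are the sum of SSB
#' and DSB ends, so the difference isolates the SSB component. Negative
#' raw differences are sampling noise, clamped to zero and counted.
#'
#' @param s1 per-depth [BinnedEndProfile-class] of the S1-treated library.
#' @param native per-depth [BinnedEndProfile-class] of the native library.
#' @return an [SSBProfile-class].
#' @export
ssbDifferential <- function(s1, native) {
  stopifnot(is(s1, "BinnedEndProfile"), is(native, "BinnedEndProfile"))
  if (s1@normalized != "per_depth" || native@normalized != "per_depth")
    stop("both profiles must be depth-normalized", call. = FALSE)
  if (s1@binWidth != native@binWidth ||
      s1@genomeLength != native@genomeLength)
    stop("profiles have mismatched binning", call. = FALSE)
  dUp <- s1@upstream - native@upstream
  dDown <- s1@downstream - native@downstream
  new("SSBProfile", binWidth = s1@binWidth, genomeLength = s1@genomeLength,
      upstream = pmax(0, dUp), downstream = pmax(0, dDown),
      normalized = "per_depth", depth = s1@depth,
      meta = list(condition = s1@meta$condition, s1Treated = NA,
                  excluded = NA_integer_),
      clampedUpstream = sum(dUp < 0), clampedDownstream = sum(dDown < 0))
}

## circular running median of v with window half-width w (2w+1 bins)
.circRunningMedian <- function(v, w) {
  n <- length(v)
  idx <- ((outer(seq_len(n), -w:w, "+") - 1L) %% n) + 1L
  apply(matrix(v[idx], nrow = n), 1L, stats::median)
}

#' Background subtraction by circular running median
#'
#' `residual(k) = value(k) - median(value[k-w .. k+w])`, with the window
#' wrapping around the coordinate origin. The local median is robust to
#' the sharp hotspot peaks being sought, and subtracting it removes both
#' the flat background and slowly varying coverage trends; subtracting a
#' constant from the profile leaves residuals unchanged.
#'
#' @param profile a [BinnedEndProfile-class] (typically per-depth) or
#'   [SSBProfile-class].
#' @param windowHalfwidth window half-width in bins, in
#'   `[1, nBins/2]` (default 25 bins, about 1 kb at 40-bp bins).
#' @return a [ResidualProfile-class].
#' @export
backgroundSubtract <- function(profile, windowHalfwidth = 25L) {
  stopifnot(is(profile, "BinnedEndProfile"))
  w <- as.integer(windowHalfwidth)
  nb <- nBins(profile)
  if (w < 1L || w > nb %/% 2L)
    stop("windowHalfwidth must lie in [1, nBins/2]", call. = FALSE)
  new("ResidualProfile", binWidth = profile@binWidth,
      genomeLength = profile@genomeLength,
      upstream = profile@upstream - .circRunningMedian(profile@upstream, w),
      downstream = profile@downstream -
        .circRunningMedian(profile@downstream, w),
      windowHalfwidth = w)
}

## bin k covers [(k-1)w+1, min(kw, L)]
.binInterval <- function(k, binWidth, L) {
  cbind(start = (k - 1L) * binWidth + 1L, end = pmin(k * binWidth, L))
}

#' Rank top hotspot bins by background-subtracted residual
#'
#' Removes bins whose interval overlaps any excluded region (by default
#' the D-loop and oriL, which carry replication-intermediate ends), sorts
#' the rest by residual descending with ties broken by lower bin index,
#' and returns the first `nTop` with ranks 1..`nTop` (fewer if fewer are
#' eligible). The exclusion applies only to ranking, never to profile
#' computation. Output is invariant under positive rescaling of the
#' residuals and independent of input order.
#'
#' @param res a [ResidualProfile-class].
#' @param endClass `"upstream"` or `"downstream"`.
#' @param exclude `data.frame(label, start, end)` of circular regions to
#'   exclude from ranking, or `NULL`.
#' @param nTop number of bins to return (default 15).
#' @return `data.frame(rank, bin, bin_start, bin_end, end_class,
#'   residual)`.
#' @export
rankTopBins <- function(res, endClass = c("upstream", "downstream"),
                        exclude = NULL, nTop = 15L) {
  stopifnot(is(res, "ResidualProfile"), nTop >= 1L)
  endClass <- match.arg(endClass)
  vals <- if (endClass == "upstream") res@upstream else res@downstream
  nb <- nBins(res)
  L <- res@genomeLength
  iv <- .binInterval(seq_len(nb), res@binWidth, L)
  eligible <- rep(TRUE, nb)
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude)))
      eligible <- eligible & !.circIntervalsOverlap(
        iv[, "start"], iv[, "end"], exclude$start[i], exclude$end[i], L)
  }
  keep <- which(eligible)
  ord <- keep[order(-vals[keep], keep)]
  top <- utils::head(ord, nTop)
  data.frame(rank = seq_along(top), bin = top,
             bin_start = iv[top, "start"], bin_end = iv[top, "end"],
             end_class = endClass, residual = vals[top],
             stringsAsFactors = FALSE)
}

#' Classify called bins as SSB, DSB or mixed
#'
#' Compares per-bin SSB-differential and native (DSB) frequencies at the
#' called bins: a bin is `SSB` when the differential exceeds `ratio`
#' times the native value, `DSB` in the opposite case, and `mixed`
#' between.
#'
#' @param calls output of [rankTopBins()].
#' @param ssb an [SSBProfile-class].
#' @param native per-depth native [BinnedEndProfile-class].
#' @param ratio dominance ratio (default 2).
#' @return `calls` with an added `break_class` column.
#' @export
classifyBreakBins <- function(calls, ssb, native, ratio = 2) {
  stopifnot(is(ssb, "SSBProfile"), is(native, "BinnedEndProfile"))
  getv <- function(p, cls, bins)
    if (cls == "upstream") p@upstream[bins] else p@downstream[bins]
  s <- mapply(function(b, cls) getv(ssb, cls, b), calls$bin, calls$end_class)
  n <- mapply(function(b, cls) getv(native, cls, b), calls$bin,
              calls$end_class)
  calls$break_class <- ifelse(s > ratio * n, "SSB",
                              ifelse(n > ratio * s, "DSB", "mixed"))
  calls
}

#' The degradation stalling-site panel
#'
#' Positions on the human mtDNA where linear degradation of broken
#' genomes stalls, with the fragment-end class at which each is read out.
#'
#' @return `data.frame(position, end_class)`.
#' @export
stallingSitePanel <- function() {
  data.frame(position = c(3210L, 5736L, 5969L, 9921L, 14249L),
             end_class = c("upstream", "upstream", "upstream",
                           "downstream", "downstream"),
             stringsAsFactors = FALSE)
}

#' Query end frequencies at specific sites
#'
#' Returns the depth-normalized end frequency at each queried site,
#' either at the exact position (when given an `EndTable` plus depth;
#' mode `per_position`) or as the containing bin's value (when given a
#' per-depth [BinnedEndProfile-class]; mode `binned`).
#'
#' @param x an `EndTable` from [extractEnds()] or a per-depth
#'   [BinnedEndProfile-class].
#' @param sites `data.frame(position, end_class)`; defaults to
#'   [stallingSitePanel()].
#' @param depth mean depth, required in per-position mode.
#' @return `data.frame(position, end_class, frequency, mode)`.
#' @export
stallingSiteQuery <- function(x, sites = stallingSitePanel(), depth = NULL) {
  if (!all(sites$end_class %in% c("upstream", "downstream")))
    stop("unknown end class in site table", call. = FALSE)
  if (inherits(x, "EndTable")) {
    if (is.null(depth))
      stop("depth is required for per-position queries", call. = FALSE)
    freq <- vapply(seq_len(nrow(sites)), function(i) {
      ends <- if (sites$end_class[i] == "upstream") x$upstream else
        x$downstream
      if (depth > 0) sum(ends == sites$position[i]) / depth else 0
    }, numeric(1))
    mode <- "per_position"
  } else if (is(x, "BinnedEndProfile")) {
    if (x@normalized != "per_depth")
      stop("profile must be depth-normalized", call. = FALSE)
    bins <- ceiling(sites$position / x@binWidth)
    freq <- vapply(seq_len(nrow(sites)), function(i) {
      v <- if (sites$end_class[i] == "upstream") x@upstream else x@downstream
      v[bins[i]]
    }, numeric(1))
    mode <- "binned"
  } else stop("x must be an EndTable or a BinnedEndProfile", call. = FALSE)
  data.frame(position = sites$position, end_class = sites$end_class,
             frequency = freq, mode = mode, stringsAsFactors = FALSE)
}
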