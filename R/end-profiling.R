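## From fragment records to binned, depth-normalized end-frequency
## profiles. Ends inside the restriction-site exclusion window are library
## artifacts and are dropped (but counted); the remaining upstream and
## downstream ends are tallied into fixed-width bins anchored at position
## 1 and divided by mean sequencing depth.

#' Extract fragment ends, applying the restriction-site exclusion
#'
#' Collects the upstream and downstream end of every mito fragment and
#' drops (counting them) any end falling inside the exclusion interval
#' around the linearization cut site, whose ends are artifacts of library
#' preparation rather than strand breaks. Nuclear records are ignored.
#'
#' @param frags fragment table (see [sampleLibrary()]).
#' @param L genome length.
#' @param exclusion `c(start, end)` circular interval to exclude, or
#'   `NULL` for none. Default: the EagI window 2550-2585.
#' @param condition library label.
#' @param s1Treated logical flag carried into profile metadata.
#' @return an `EndTable`: `list(upstream, downstream, excluded, L,
#'   condition, s1Treated)` with retained end positions per class.
#' @export
extractEnds <- function(frags, L, exclusion = c(2550L, 2585L),
                        condition = "", s1Treated = FALSE) {
  mito <- frags[frags$compartment == "mito", , drop = FALSE]
  up <- as.integer(mito$upstream_end)
  down <- as.integer(mito$downstream_end)
  if (length(up)) .checkPositions(up, L, "upstream end")
  if (length(down)) .checkPositions(down, L, "downstream end")
  excluded <- 0L
  if (!is.null(exclusion) && length(up)) {
    exUp <- intervalContains(up, exclusion[1], exclusion[2], L)
    exDown <- intervalContains(down, exclusion[1], exclusion[2], L)
    excluded <- sum(exUp) + sum(exDown)
    up <- up[!exUp]
    down <- down[!exDown]
  }
  structure(list(upstream = up, downstream = down, excluded = excluded,
                 L = as.integer(L), condition = condition,
                 s1Treated = isTRUE(s1Treated)),
            class = "EndTable")
}

#' Bin fragment ends
#'
#' Bin `k` (1-based) covers positions `[(k-1)*binWidth + 1, k*binWidth]`
#' clipped at `L`; each retained end increments exactly one bin, so bin
#' sums equal retained end counts. For the human mtDNA (L = 16,569) at the
#' default 40-bp width there are 415 bins, the last covering 16,561-16,569.
#'
#' @param ends an `EndTable` from [extractEnds()].
#' @param binWidth bin width in bp (default 40).
#' @return a [BinnedEndProfile-class] of raw counts.
#' @export
binEnds <- function(ends, binWidth = 40L) {
  stopifnot(inherits(ends, "EndTable"), binWidth >= 1L)
  L <- ends$L
  nb <- as.integer(ceiling(L / binWidth))
  new("BinnedEndProfile", binWidth = as.integer(binWidth), genomeLength = L,
      upstream = as.numeric(tabulate(ceiling(ends$upstream / binWidth), nb)),
      downstream = as.numeric(tabulate(ceiling(ends$downstream / binWidth), nb)),
      normalized = "raw_counts", depth = NA_real_,
      meta = list(condition = ends$condition, s1Treated = ends$s1Treated,
                  excluded = ends$excluded))
}

#' Mean sequencing depth of a fragment library
#'
#' Sum of mito fragment lengths divided by genome length: the average
#' per-base coverage the retained (post-size-selection) fragments provide.
#'
#' @param frags fragment table.
#' @param L genome length (> 0).
#' @return mean depth (0 for an empty library).
#' @export
meanDepth <- function(frags, L) {
  if (L <= 0) stop("genome length must be positive", call. = FALSE)
  mito <- frags[frags$compartment == "mito", , drop = FALSE]
  if (!nrow(mito)) return(0)
  sum(as.numeric(mito$length)) / L
}

#' Normalize a binned profile to mean sequencing depth
#'
#' Divides every bin value by the mean depth, making profiles comparable
#' across libraries sequenced to different depths (5 ends in a bin at
#' depth 100 become 0.05).
#'
#' @param profile a raw-count [BinnedEndProfile-class].
#' @param depth mean depth from [meanDepth()] (> 0).
#' @return a per-depth [BinnedEndProfile-class].
#' @export
normalizeToDepth <- function(profile, depth) {
  stopifnot(is(profile, "BinnedEndProfile"))
  if (!is.finite(depth) || depth <= 0)
    stop("depth must be positive for normalization", call. = FALSE)
  if (profile@normalized != "raw_counts")
    stop("profile is already normalized", call. = FALSE)
  initialize(profile, upstream = profile@upstream / depth,
             downstream = profile@downstream / depth,
             normalized = "per_depth", depth = depth)
}

#' Fragment size distribution over fixed size classes
#'
#' Tallies fragment lengths into half-open classes `[lower, upper)`
#' (default 500-bp classes from 0 to 20 kb plus an overflow class) and
#' returns per-class proportions. Used for the nuclear length-bias
#' normalization and for comparing fragmentation between libraries.
#'
#' @param lengths fragment lengths in bp.
#' @param edges class boundaries; class `i` is `[edges[i], edges[i+1])`.
#' @return `data.frame(lower, upper, proportion)`; proportions sum to 1
#'   (all zero for empty input).
#' @export
fragmentSizeDistribution <- function(lengths,
                                     edges = c(seq(0, 20000, by = 500), Inf)) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges))
  k <- length(edges) - 1L
  counts <- tabulate(findInterval(lengths, edges), k)
  prop <- if (length(lengths)) counts / length(lengths) else rep(0, k)
  data.frame(lower = edges[-length(edges)], upper = edges[-1L],
             proportion = prop)
}

.checkSameEdges <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$lower != b$lower) ||
      !all(a$upper == b$upper | (is.infinite(a$upper) & is.infinite(b$upper))))
    stop("size distributions have mismatched class edges", call. = FALSE)
}

#' Length-bias weights from nuclear size distributions
#'
#' Per-size-class weights `reference / sample` that reweight a sample's
#' fragment counts to the nuclear size distribution of the reference
#' experiment (the one with the highest proportion of large fragments),
#' correcting experiment-to-experiment read-length bias. Classes with zero
#' sample proportion get weight 0 and are reported.
#'
#' @param sampleDist,referenceDist size distributions from
#'   [fragmentSizeDistribution()] with identical class edges.
#' @return `data.frame(lower, upper, weight)` with attribute
#'   `zeroClasses`: indices of sample classes with zero proportion but
#'   positive reference proportion.
#' @export
lengthBiasWeights <- function(sampleDist, referenceDist) {
  .checkSameEdges(sampleDist, referenceDist)
  w <- ifelse(sampleDist$proportion > 0,
              referenceDist$proportion / sampleDist$proportion, 0)
  zero <- which(sampleDist$proportion == 0 & referenceDist$proportion > 0)
  if (length(zero))
    warning(sprintf("%d size class(es) empty in sample but not reference; weight 0",
                    length(zero)))
  structure(data.frame(lower = sampleDist$lower, upper = sampleDist$upper,
                       weight = w),
            zeroClasses = zero)
}

#' Select the reference library for length-bias normalization
#'
#' Returns the index of the library whose nuclear size distribution has
#' the highest summed proportion of large fragments (classes with lower
#' edge at or above `largeThreshold`); ties go to the first library.
#'
#' @param distributions list of size distributions with identical edges.
#' @param largeThreshold "large fragment" lower bound in bp (default
#'   10 kb).
#' @return index of the selected library.
#' @export
selectReferenceLibrary <- function(distributions, largeThreshold = 10000) {
  if (!length(distributions)) stop("no libraries supplied", call. = FALSE)
  for (d in distributions[-1L]) .checkSameEdges(distributions[[1L]], d)
  score <- vapply(distributions, function(d)
    sum(d$proportion[d$lower >= largeThreshold]), numeric(1))
  which.max(score)  # which.max takes the first maximum: documented tie-break
}

#' Compare two fragment size distributions
#'
#' Reports per-class proportion differences (`a - b`), the difference in
#' the full-length class (the class containing `fullLength`), and the
#' total variation distance `0.5 * sum(|a - b|)` in `[0, 1]`. A shift of
#' mass from the full-length class to shorter classes indicates increased
#' fragmentation.
#'
#' @param a,b size distributions with identical edges.
#' @param fullLength genome length locating the full-length class
#'   (default human mtDNA, 16,569 bp).
#' @return `list(perClass, totalVariation, fullLengthDiff)`.
#' @export
compareSizeDistributions <- function(a, b, fullLength = 16569) {
  .checkSameEdges(a, b)
  diff <- a$proportion - b$proportion
  fl <- which(a$lower <= fullLength & fullLength < a$upper)
  list(perClass = data.frame(lower = a$lower, upper = a$upper, diff = diff),
       totalVariation = 0.5 * sum(abs(diff)),
       fullLengthDiff = if (length(fl)) diff[fl[1L]] else NA_real_)
}
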