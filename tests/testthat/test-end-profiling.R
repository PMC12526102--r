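mtGenome <- CircularGenome("synthetic_mt", length = 16569)
L <- 16569L

test_that("extractEnds drops and counts ends in the exclusion window", {
  full <- data.frame(compartment = "mito", upstream_end = 2568L,
                     downstream_end = 2567L, length = 16569L,
                     origin_spanning = TRUE)
  et <- extractEnds(full, L, exclusion = c(2550L, 2585L))
  expect_length(et$upstream, 0)
  expect_length(et$downstream, 0)
  expect_equal(et$excluded, 2L)

  fr <- data.frame(compartment = "mito", upstream_end = 3211L,
                   downstream_end = 2567L, length = 15926L,
                   origin_spanning = TRUE)
  et2 <- extractEnds(fr, L, exclusion = c(2550L, 2585L))
  expect_equal(et2$upstream, 3211L)
  expect_length(et2$downstream, 0)
  expect_equal(et2$excluded, 1L)

  empty <- extractEnds(full[0, ], L)
  expect_length(empty$upstream, 0)
  expect_equal(empty$excluded, 0L)
  # nuclear records are ignored
  nuc <- data.frame(compartment = "nuclear", upstream_end = NA_integer_,
                    downstream_end = NA_integer_, length = 8000L,
                    origin_spanning = NA)
  expect_length(extractEnds(nuc, L)$upstream, 0)
})

test_that("end conservation: retained + excluded == 2 x mito fragments", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    up <- sample.int(L, n, replace = TRUE)
    down <- sample.int(L, n, replace = TRUE)
    fr <- data.frame(compartment = "mito", upstream_end = up,
                     downstream_end = down, length = 5000L,
                     origin_spanning = FALSE)
    et <- extractEnds(fr, L, exclusion = c(2550L, 2585L))
    expect_equal(length(et$upstream) + length(et$downstream) + et$excluded,
                 2L * n)
  }
})

test_that("binEnds uses 1-anchored bins with a short final bin", {
  mk <- function(pos) structure(list(upstream = pos, downstream = integer(0),
                                     excluded = 0L, L = L, condition = "",
                                     s1Treated = FALSE), class = "EndTable")
  p <- binEnds(mk(c(40L, 41L)), 40L)
  expect_equal(nBins(p), 415L)
  expect_equal(upstreamValues(p)[1:2], c(1, 1))
  # last bin covers 16561-16569 (width 9)
  p2 <- binEnds(mk(c(16561L, 16569L)), 40L)
  expect_equal(upstreamValues(p2)[415], 2)
  set.seed(42)
  pos <- sample.int(L, 1000, replace = TRUE)
  p3 <- binEnds(mk(pos), 40L)
  expect_equal(sum(upstreamValues(p3)), 1000)
})

test_that("binEnds agrees with the per-position brute-force tally", {
  set.seed(43)
  for (i in 1:30) {
    Lx <- sample(50:400, 1)
    w <- sample(3:25, 1)
    pos <- sample.int(Lx, sample(1:200, 1), replace = TRUE)
    et <- structure(list(upstream = pos, downstream = integer(0),
                         excluded = 0L, L = Lx, condition = "",
                         s1Treated = FALSE), class = "EndTable")
    expect_equal(upstreamValues(binEnds(et, w)), as.numeric(bruteBin(pos, w, Lx)),
                 info = sprintf("L=%d w=%d", Lx, w))
  }
})

test_that("meanDepth and depth normalization follow sum(length)/L", {
  fl <- function(lens) data.frame(compartment = rep("mito", length(lens)),
                                  upstream_end = rep(1L, length(lens)),
                                  downstream_end = rep(2L, length(lens)),
                                  length = lens,
                                  origin_spanning = rep(FALSE, length(lens)))
  expect_equal(meanDepth(fl(16569L), L), 1)
  expect_equal(meanDepth(fl(c(3000L, 13569L)), L), 1)
  expect_equal(meanDepth(fl(integer(0)), L), 0)
  expect_error(meanDepth(fl(100L), 0), "positive")

  et <- structure(list(upstream = rep(15L, 5), downstream = integer(0),
                       excluded = 0L, L = L, condition = "",
                       s1Treated = FALSE), class = "EndTable")
  prof <- binEnds(et, 40L)
  norm <- normalizeToDepth(prof, 100)
  expect_equal(upstreamValues(norm)[1], 0.05)
  expect_equal(upstreamValues(normalizeToDepth(prof, 1)),
               upstreamValues(prof))
  expect_error(normalizeToDepth(prof, 0), "positive")
  expect_error(normalizeToDepth(norm, 2), "already")
})

test_that("depth normalization cancels sampling-depth differences", {
  hs <- data.frame(position = c(3210, 14249), kind = c("dsb", "dsb"),
                   rate = c(0.2, 0.2))
  prof <- function(n, seed) {
    cfg <- simulationConfig(mtGenome, hotspots = hs, eagIEfficiency = 1,
                            nMolecules = n, seed = seed)
    lib <- sampleLibrary(cfg)
    normalizeToDepth(binEnds(extractEnds(lib, L), 40L), meanDepth(lib, L))
  }
  shallow <- prof(800, 1)
  deep <- prof(3200, 2)   # 4x depth, same break structure
  b <- ceiling(3211 / 40)
  expect_lt(abs(upstreamValues(shallow)[b] - upstreamValues(deep)[b]),
            0.35 * upstreamValues(deep)[b])
})

test_that("rotation equivariance of binned profiles (L a bin-width multiple)", {
  Lr <- 16560L
  shift <- 4000L   # 100 bins of 40 bp
  set.seed(44)
  up <- sample.int(Lr, 500, replace = TRUE)
  down <- sample.int(Lr, 500, replace = TRUE)
  mk <- function(u, d, ex) extractEnds(
    data.frame(compartment = "mito", upstream_end = u, downstream_end = d,
               length = 5000L, origin_spanning = FALSE),
    Lr, exclusion = ex)
  ex <- c(2550L, 2585L)
  p0 <- binEnds(mk(up, down, ex), 40L)
  p1 <- binEnds(mk(rotateCoordinates(up, shift, Lr),
                   rotateCoordinates(down, shift, Lr),
                   rotateCoordinates(ex, shift, Lr)), 40L)
  rot <- function(v, k) c(tail(v, -((length(v) - k))), head(v, length(v) - k))
  expect_equal(upstreamValues(p1), rot(upstreamValues(p0), 100L))
  expect_equal(downstreamValues(p1), rot(downstreamValues(p0), 100L))
})

test_that("size distributions, reference selection and bias weights", {
  d <- fragmentSizeDistribution(c(250, 250, 750, 19999, 25000))
  expect_equal(sum(d$proportion), 1)
  expect_equal(d$proportion[1], 0.4)          # [0, 500)
  expect_equal(d$proportion[nrow(d)], 0.2)    # overflow class

  edges <- c(0, 10, 20)
  mkd <- function(p) data.frame(lower = edges[-3], upper = edges[-1],
                                proportion = p)
  expect_equal(lengthBiasWeights(mkd(c(0.5, 0.5)), mkd(c(0.5, 0.5)))$weight,
               c(1, 1))
  w <- lengthBiasWeights(mkd(c(0.5, 0.5)), mkd(c(0.25, 0.75)))
  expect_equal(w$weight, c(0.5, 1.5))
  # reweighted sample counts reproduce the reference proportions
  counts <- c(40, 40)
  rw <- counts * w$weight
  expect_equal(rw / sum(rw), c(0.25, 0.75))
  expect_warning(w0 <- lengthBiasWeights(mkd(c(0, 1)), mkd(c(0.25, 0.75))),
                 "empty in sample")
  expect_equal(w0$weight[1], 0)
  expect_equal(attr(w0, "zeroClasses"), 1L)
  expect_error(lengthBiasWeights(mkd(c(0.5, 0.5)),
                                 data.frame(lower = c(0, 5), upper = c(5, 10),
                                            proportion = c(0.5, 0.5))),
               "mismatched")

  dists <- list(mkd(c(0.9, 0.1)), mkd(c(0.6, 0.4)), mkd(c(0.8, 0.2)))
  expect_equal(selectReferenceLibrary(dists, largeThreshold = 10), 2L)
  expect_equal(selectReferenceLibrary(dists[c(2, 2)], largeThreshold = 10), 1L)
  expect_equal(selectReferenceLibrary(dists[1], largeThreshold = 10), 1L)
  expect_error(selectReferenceLibrary(list()), "no libraries")
})

test_that("compareSizeDistributions reports TV distance and full-length shift", {
  edges <- c(0, 10000, 17000)
  mkd <- function(p) data.frame(lower = edges[-3], upper = edges[-1],
                                proportion = p)
  same <- compareSizeDistributions(mkd(c(0.5, 0.5)), mkd(c(0.5, 0.5)))
  expect_equal(same$totalVariation, 0)
  expect_equal(same$perClass$diff, c(0, 0))
  expect_equal(compareSizeDistributions(mkd(c(1, 0)),
                                        mkd(c(0, 1)))$totalVariation, 1)
  cmp <- compareSizeDistributions(mkd(c(0.6, 0.4)), mkd(c(0.4, 0.6)))
  expect_equal(cmp$totalVariation, 0.2)
  expect_equal(cmp$fullLengthDiff, -0.2)  # class containing 16,569 bp
})
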