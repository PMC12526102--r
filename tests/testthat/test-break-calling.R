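mtGenome <- CircularGenome("synthetic_mt", length = 16569)
L <- 16569L

mkProfile <- function(up, down = up, w = 40L, Lx = L,
                      normalized = "per_depth", depth = 1) {
  new("BinnedEndProfile", binWidth = w, genomeLength = as.integer(Lx),
      upstream = up, downstream = down, normalized = normalized,
      depth = depth, meta = list())
}

test_that("ssbDifferential clamps at zero and counts clamped bins", {
  nb <- 415L
  nat <- mkProfile(rep(0.004, nb))
  s1 <- mkProfile(rep(0.004, nb))
  d0 <- ssbDifferential(s1, nat)
  expect_true(all(upstreamValues(d0) == 0))
  expect_equal(d0@clampedUpstream, 0L)

  s1v <- rep(0.004, nb); s1v[10] <- 0.010; s1v[20] <- 0.001
  d1 <- ssbDifferential(mkProfile(s1v), nat)
  expect_equal(upstreamValues(d1)[10], 0.006)
  expect_equal(upstreamValues(d1)[20], 0)     # clamped
  expect_equal(d1@clampedUpstream, 1L)
  expect_error(ssbDifferential(mkProfile(rep(1, nb), normalized = "per_depth"),
                               mkProfile(rep(0L, nb),
                                         normalized = "raw_counts")),
               "depth-normalized")
  expect_error(ssbDifferential(mkProfile(rep(0.1, 415)),
                               mkProfile(rep(0.1, 829), w = 20L)),
               "mismatched")
})

test_that("adding native back reconstructs S1 where no clamping occurred", {
  set.seed(51)
  nb <- 415L
  nat <- mkProfile(runif(nb, 0, 0.01))
  s1 <- mkProfile(upstreamValues(nat) + runif(nb, 0, 0.02))
  d <- ssbDifferential(s1, nat)
  expect_equal(d@clampedUpstream, 0L)
  expect_equal(upstreamValues(d) + upstreamValues(nat), upstreamValues(s1))
})

test_that("backgroundSubtract is a circular running-median residual", {
  nb <- 415L
  const <- mkProfile(rep(0.3, nb))
  expect_true(all(upstreamValues(backgroundSubtract(const, 25L)) == 0))

  spike <- rep(0, nb); spike[200] <- 7
  r <- backgroundSubtract(mkProfile(spike), 5L)
  expect_equal(upstreamValues(r)[200], 7)
  expect_true(all(upstreamValues(r)[-200] <= 0))

  # two-bin plateau on a constant baseline
  v <- rep(1, nb); v[50:51] <- 4
  r2 <- backgroundSubtract(mkProfile(v), 5L)
  expect_equal(upstreamValues(r2)[50:51], c(3, 3))
  expect_equal(upstreamValues(r2)[200], 0)
  expect_error(backgroundSubtract(const, 0L), "windowHalfwidth")
  expect_error(backgroundSubtract(const, 300L), "windowHalfwidth")
})

test_that("circular running median agrees with the tripled-vector oracle", {
  set.seed(52)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    w <- sample(1:max(1, n %/% 2 - 1), 1)
    v <- round(runif(n, 0, 10), 2)
    expect_equal(mtbreaks:::.circRunningMedian(v, w), bruteCircMedian(v, w),
                 info = sprintf("n=%d w=%d", n, w))
  }
})

test_that("background subtraction is location-invariant", {
  set.seed(53)
  v <- runif(415, 0, 0.01)
  r1 <- upstreamValues(backgroundSubtract(mkProfile(v), 25L))
  r2 <- upstreamValues(backgroundSubtract(mkProfile(v + 5), 25L))
  expect_equal(r1, r2)
})

test_that("rankTopBins ranks by residual with coordinate tie-break and exclusions", {
  nb <- 415L
  mkRes <- function(up) new("ResidualProfile", binWidth = 40L,
                            genomeLength = L, upstream = up,
                            downstream = rep(0, nb), windowHalfwidth = 25L)
  flat <- rankTopBins(mkRes(rep(1, nb)), "upstream", nTop = 5L)
  expect_equal(flat$bin, 1:5)                 # tie-break by coordinate
  expect_equal(flat$rank, 1:5)

  v <- rep(0, nb); v[145] <- 9; v[10] <- 5; v[300] <- 5
  top <- rankTopBins(mkRes(v), "upstream", nTop = 3L)
  expect_equal(top$bin, c(145L, 10L, 300L))
  expect_equal(top$bin_start[1], 5761L)

  # a spike inside oriL (5770-5820) must be absent when excluded
  oriL <- data.frame(label = "oriL", start = 5770L, end = 5820L)
  top2 <- rankTopBins(mkRes(v), "upstream", exclude = oriL, nTop = 3L)
  expect_false(145L %in% top2$bin)
  expect_equal(top2$bin[1:2], c(10L, 300L))

  # invariance under positive rescaling
  expect_equal(rankTopBins(mkRes(v * 1000), "upstream", nTop = 10L)$bin,
               rankTopBins(mkRes(v), "upstream", nTop = 10L)$bin)
})

test_that("ranking exclusion covers origin-spanning regions", {
  nb <- 415L
  v <- rep(0, nb); v[1] <- 3; v[414] <- 2; v[100] <- 1
  res <- new("ResidualProfile", binWidth = 40L, genomeLength = L,
             upstream = v, downstream = rep(0, nb), windowHalfwidth = 25L)
  dloop <- data.frame(label = "D-loop", start = 16030L, end = 570L)
  top <- rankTopBins(res, "upstream", exclude = dloop, nTop = 3L)
  expect_false(any(c(1L, 414L) %in% top$bin))  # both sides of the origin
  expect_equal(top$bin[1], 100L)
})

test_that("nick-only hotspots surface in the SSB differential, not the native profile", {
  hs <- data.frame(position = 9000, kind = "nick_heavy", rate = 0.3)
  cfg <- simulationConfig(mtGenome, hotspots = hs,
                          backgroundNickRate = 1e-5, eagIEfficiency = 1,
                          nMolecules = 1500, seed = 60)
  pair <- simulatePair(cfg)
  profs <- lapply(pair[c("native", "s1")], function(lib)
    normalizeToDepth(binEnds(extractEnds(lib, L), 40L), meanDepth(lib, L)))
  ssb <- ssbDifferential(profs$s1, profs$native)
  b <- ceiling(9001 / 40)
  expect_gt(upstreamValues(ssb)[b], 10 * median(upstreamValues(ssb)[-b]))
  # native profile flat at the nick bin within sampling error
  natCount <- upstreamValues(profs$native)[b] * profs$native@depth
  expect_lte(natCount, 3 * sqrt(max(natCount, 1)))
})

test_that("stallingSiteQuery works per-position and binned", {
  panel <- stallingSitePanel()
  expect_equal(panel$position, c(3210L, 5736L, 5969L, 9921L, 14249L))
  expect_equal(panel$end_class,
               c("upstream", "upstream", "upstream",
                 "downstream", "downstream"))

  et <- structure(list(upstream = c(rep(3210L, 4), 100L),
                       downstream = rep(14249L, 2), excluded = 0L, L = L,
                       condition = "", s1Treated = FALSE),
                  class = "EndTable")
  q <- stallingSiteQuery(et, depth = 1000)
  expect_equal(q$mode, rep("per_position", 5))
  expect_equal(q$frequency[q$position == 3210], 0.004)
  expect_equal(q$frequency[q$position == 14249], 0.002)
  expect_equal(q$frequency[q$position == 5736], 0)

  emptyEt <- structure(list(upstream = integer(0), downstream = integer(0),
                            excluded = 0L, L = L, condition = "",
                            s1Treated = FALSE), class = "EndTable")
  expect_true(all(stallingSiteQuery(emptyEt, depth = 0)$frequency == 0))
  expect_error(stallingSiteQuery(et, sites = data.frame(position = 1,
                                                        end_class = "left"),
                                 depth = 1),
               "unknown end class")
})

test_that("stalling-site frequencies recover the simulated truth", {
  r <- 0.2; n <- 3000L
  hs <- data.frame(position = 5736, kind = "dsb", rate = r)
  cfg <- simulationConfig(mtGenome, hotspots = hs, eagIEfficiency = 1,
                          backgroundNickRate = 0, nMolecules = n, seed = 61)
  lib <- sampleLibrary(cfg)
  depth <- meanDepth(lib, L)
  et <- extractEnds(lib, L)
  q <- stallingSiteQuery(et, sites = data.frame(
    position = c(5737L, 5736L), end_class = c("upstream", "downstream")),
    depth = depth)
  # a DSB at p leaves its upstream end at p+1 and downstream end at p;
  # both flanking arcs (3169 and 13400 bp) survive size selection here
  expTruth <- r * n / depth
  expect_lt(abs(q$frequency[1] - expTruth) / expTruth, 3 / sqrt(r * n))
  expect_lt(abs(q$frequency[2] - expTruth) / expTruth, 3 / sqrt(r * n))
})

test_that("classifyBreakBins separates SSB, DSB and mixed bins", {
  nb <- 415L
  ssb <- new("SSBProfile", binWidth = 40L, genomeLength = L,
             upstream = replace(rep(0, nb), c(10, 30), c(0.05, 0.01)),
             downstream = rep(0, nb), normalized = "per_depth", depth = 1,
             meta = list(), clampedUpstream = 0L, clampedDownstream = 0L)
  nat <- mkProfile(replace(rep(0, nb), c(20, 30), c(0.05, 0.012)))
  calls <- data.frame(bin = c(10L, 20L, 30L), end_class = "upstream")
  cl <- classifyBreakBins(calls, ssb, nat)
  expect_equal(cl$break_class, c("SSB", "DSB", "mixed"))
})
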