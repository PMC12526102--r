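# Independent brute-force oracles and synthetic fixtures. The oracles
# deliberately use a different mechanism from the implementation
# (stepwise walks on the circle, per-position scans, a recursive pattern
# matcher) so that agreement is informative.

# random circular genome sequence; optionally plant motif strings at
# given positions (1-based, may wrap)
makeTestGenome <- function(L = 2000L, seed = 1L, plant = list(),
                           name = "synthetic") {
  set.seed(seed)
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (p in plant) {
    idx <- ((p$at - 1L + seq_len(nchar(p$motif)) - 1L) %% L) + 1L
    ch[idx] <- strsplit(p$motif, "")[[1]]
  }
  CircularGenome(name, sequence = paste(ch, collapse = ""),
                 regions = data.frame(label = character(0),
                                      start = integer(0), end = integer(0)))
}

# clockwise step count from a to b, then take the smaller arc
bruteCircDist <- function(a, b, L) {
  steps <- 0L; p <- a
  while (p != b) { p <- if (p == L) 1L else p + 1L; steps <- steps + 1L }
  min(steps, L - steps)
}

# walk the clockwise arc start..end and look for p
bruteContains <- function(p, start, end, L) {
  pos <- start
  repeat {
    if (pos == p) return(TRUE)
    if (pos == end) return(FALSE)
    pos <- if (pos == L) 1L else pos + 1L
  }
}

# per-end linear scan over bin intervals
bruteBin <- function(positions, binWidth, L) {
  nb <- ceiling(L / binWidth)
  counts <- integer(nb)
  for (p in positions) {
    for (k in seq_len(nb)) {
      lo <- (k - 1L) * binWidth + 1L
      hi <- min(k * binWidth, L)
      if (p >= lo && p <= hi) { counts[k] <- counts[k] + 1L; break }
    }
  }
  counts
}

# circular running median via an explicitly tripled vector
bruteCircMedian <- function(v, w) {
  n <- length(v)
  v3 <- c(v, v, v)
  vapply(seq_len(n), function(k) median(v3[(n + k - w):(n + k + w)]),
         numeric(1))
}

# maximal circular G/C runs by per-position walking
bruteGCRuns <- function(seq, minRun) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  gc <- ch %in% c("G", "C")
  if (all(gc)) return(data.frame(start = 1L, end = L, length = L))
  prev <- function(p) if (p == 1L) L else p - 1L
  nxt <- function(p) if (p == L) 1L else p + 1L
  starts <- which(gc & !gc[vapply(seq_len(L), prev, integer(1))])
  rows <- lapply(starts, function(s) {
    e <- s; len <- 1L
    while (gc[nxt(e)]) { e <- nxt(e); len <- len + 1L }
    data.frame(start = s, end = e, length = len)
  })
  out <- do.call(rbind, rows)
  out[out$length >= minRun, , drop = FALSE]
}

# recursive lazy matcher for the four-tract G4 rule: shortest match at a
# given start, exploring fewest-repetitions-first like a lazy regex
bruteG4MatchAt <- function(ch, i, minTract = 3L, maxLoop = 7L) {
  n <- length(ch)
  runG <- function(pos) {
    r <- 0L
    while (pos + r <= n && ch[pos + r] == "G") r <- r + 1L
    r
  }
  rec <- function(pos, tractsLeft) {
    g <- runG(pos)
    if (g < minTract) return(NA_integer_)
    for (t in minTract:g) {
      after <- pos + t
      if (tractsLeft == 1L) return(after - 1L)
      for (l in seq_len(maxLoop)) {
        if (after + l > n) break
        res <- rec(after + l, tractsLeft - 1L)
        if (!is.na(res)) return(res)
      }
    }
    NA_integer_
  }
  rec(i, 4L)
}

# leftmost non-overlapping circular scan on the doubled sequence,
# mirroring the implementation's conventions but not its engine
bruteG4Heavy <- function(seq) {
  L <- nchar(seq)
  ch <- strsplit(paste0(seq, seq), "")[[1]]
  out <- data.frame(start = integer(0), end = integer(0))
  i <- 1L
  while (i <= L) {
    e <- bruteG4MatchAt(ch, i)
    if (!is.na(e) && (e - i + 1L) <= L) {
      out <- rbind(out, data.frame(start = i, end = ((e - 1L) %% L) + 1L))
      i <- e + 1L
    } else i <- i + 1L
  }
  out
}

# simple paired-library simulation wrapper used across tests
simulatePair <- function(cfg) {
  set.seed(cfg$seed)
  mols <- simulateMolecules(cfg, seed = NULL)
  native <- mtbreaks:::.assembleLibrary(mols, cfg)
  s1 <- mtbreaks:::.assembleLibrary(lapply(mols, s1Treat), cfg)
  list(molecules = mols, native = native, s1 = s1)
}
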