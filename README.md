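# mtbreaks

Strand-break end profiling and turnover kinetics for circular
mitochondrial genomes.

## The problem

Mitochondrial DNA (mtDNA) is a multicopy circular genome (human
reference length 16,569 bp) that is continuously damaged and turned
over. Two experimental readouts make this damage measurable:

1. **Long-read fragment-end profiling.** Isolated mtDNA is linearized
   with a single-cutter restriction enzyme (EagI), size-selected to
   remove fragments < 3 kb, and sequenced as single molecules. Every
   fragment end that is not the restriction cut marks a double-strand
   break (DSB). Treating a parallel sample with S1 nuclease first
   converts single-strand breaks (SSBs — nicks and gaps) into DSBs, so
   ends in the S1-treated library represent SSB + DSB and the
   *difference* between paired libraries isolates the SSB component.
2. **Turnover kinetics.** The decay of BrdU-labeled mtDNA, copy-number
   depletion under the replication inhibitor ddC, and qPCR copy-number
   measurements quantify how fast broken genomes are degraded and
   replaced.

`mtbreaks` implements the full analysis as a tested R package:

- **Circular coordinate arithmetic** (`circDistance`,
  `intervalContains`, `rotateCoordinates`): 1-based inclusive positions
  on the circle; intervals with `start > end` (such as the D-loop,
  16030–570) are first-class.
- **A generative simulator** (`simulationConfig`, `sampleLibrary`,
  `runSimulate`): populations of circles carrying strand-specific nicks
  and DSBs at planted hotspots plus Poisson background, S1 conversion
  (`s1Treat`), single-cutter linearization, size selection, and nuclear
  background fragments — so every downstream stage is testable against
  known truth without any sequencing data.
- **End profiling** (`extractEnds`, `binEnds`, `normalizeToDepth`):
  upstream/downstream ends per fragment, exclusion of artifact ends near
  the restriction site (positions 2550–2585), 40-nt binning, and
  normalization to average sequencing depth
  (`depth = sum(fragment lengths) / L`).
- **Break calling** (`ssbDifferential`, `backgroundSubtract`,
  `rankTopBins`): per-bin SSB estimate `max(0, S1 − native)`, circular
  running-median background subtraction, and ranking of the top residual
  bins excluding regions dominated by replication intermediates (D-loop,
  oriL). `stallingSiteQuery` reads out depth-normalized end frequencies
  at the degradation stalling-site panel (3210, 5736, 5969 upstream;
  9921, 14249 downstream).
- **Motif annotation** (`findGCStretches`, `findG4Motifs`,
  `annotateHotspots`, `rotationAssociationTest`): maximal GC runs and
  the four-tract G-quadruplex rule `G{3,}(N{1,7}G{3,}){3}` on both
  strands, with a circular rotation-permutation association test.
- **Kinetics** (`fitExponential`, `decomposeDilution`, `chapmanFit`,
  `copyNumber`, `fitDepletionRepopulation`): half-life `ln(2)/k` from
  log-linear decay fits; degradation vs. division-dilution decomposition
  `k_deg = k_apparent − ln(2)/t_double`; qPCR quantification cycles from
  the inflection `Ct = ln(c)/b` of the four-parameter Chapman curve
  `y = y0 + a(1 − e^(−bx))^c`; copies per cell
  `2 · efficiency^(Ct_nuclear − Ct_mito)`.

## Worked example

Simulate a paired native/S1 experiment with two nick hotspots and one
DSB hotspot, then run the calling chain:

```r
library(mtbreaks)

mt <- CircularGenome("human_mt", length = 16569)  # regions attached
hotspots <- data.frame(position = c(3210, 8000, 14249),
                       kind = c("nick_heavy", "nick_heavy", "dsb"),
                       rate = c(0.05, 0.05, 0.05))
cfg <- simulationConfig(mt, hotspots = hotspots,
                        backgroundNickRate = 1e-5,
                        nMolecules = 5000, seed = 11)
sim <- runSimulate(cfg, tempdir())
res <- runProfileAndCall(sim$native, sim$s1, mt)
head(res$callsUpstream[, c("rank", "bin", "bin_start", "bin_end",
                           "residual", "break_class")], 5)
```

```
 rank bin bin_start bin_end    residual break_class
    1  81      3201    3240 0.052146756         SSB
    2 357     14241   14280 0.050632120         DSB
    3 201      8001    8040 0.049982990         SSB
    4  72      2841    2880 0.001514636         SSB
    5 258     10281   10320 0.001081883         SSB
```

The three planted hotspots dominate the ranking and are classified
correctly: a break at position *p* leaves its upstream end at *p* + 1,
so the nick at 3210 surfaces in bin 81 (positions 3201–3240) of the
S1-treated library only (`SSB`), while the DSB at 14249 also appears in
the native library (`DSB`). Residuals are per-depth end frequencies
above the local background; the remaining ranks are sampling noise an
order of magnitude lower.

```r
stallingSiteQuery(res$s1)
```

```
 position  end_class    frequency   mode
     3210   upstream 0.0527958854 binned
     5736   upstream 0.0002163766 binned
     5969   upstream 0.0004327532 binned
     9921 downstream 0.0004327532 binned
    14249 downstream 0.0506321196 binned
```

The hotspot sites stand ~100× above the background sites (frequencies
are ends per unit depth: ≈ 0.05 matches the planted per-molecule rate).

Kinetics, on the bundled pulse-chase endpoint table:

```r
chase <- runKinetics(system.file("extdata", "brdu_chase.tsv",
                                 package = "mtbreaks"),
                     doublingTime = 30)
chase[, c("label", "half_life_h", "degradation_half_life_h",
          "dilution_dominated")]
```

```
     label half_life_h degradation_half_life_h dilution_dominated
   clone_a    12.00000                20.00000              FALSE
   clone_b    20.26300                62.43097              FALSE
 wild_type    21.42294                74.93110              FALSE
```

A signal falling to 0.25 of baseline in 24 h is an apparent half-life of
exactly 12 h; at a 30-h doubling time, dilution alone would give a 30-h
half-life, so the degradation component has a 20-h half-life.

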