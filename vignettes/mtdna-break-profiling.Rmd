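---
title: "Mapping mtDNA strand breaks from fragment ends: methods and design"
author: "mtbreaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mtDNA strand breaks from fragment ends: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbreaks)
```

# The measurement model

Mitochondrial DNA is a circular, multicopy genome. When isolated mtDNA
is linearized by a single-cutter restriction enzyme and sequenced as
single long molecules, every fragment terminus that is not the
restriction cut marks a pre-existing double-strand break (DSB). S1
nuclease converts single-strand breaks (SSBs: nicks and gaps) into
DSBs, so ends observed in an S1-treated aliquot represent the sum of
SSBs and DSBs, and the paired difference

$$\widehat{\mathrm{SSB}}_k \;=\; \max\!\bigl(0,\; f^{S1}_k - f^{\mathrm{nat}}_k\bigr)$$

per genomic bin $k$ isolates the SSB component. `mtbreaks` implements
this measurement model end to end, together with the kinetic analyses
(label-chase decay, replication-arrest depletion, qPCR copy number)
that quantify mtDNA turnover.

Coordinates are 1-based inclusive throughout, following mtDNA community
numbering; file formats using 0-based half-open coordinates (BED) are
converted at the boundary by `readFragmentBed()`, and that conversion is
tested. Intervals with `start > end` span the coordinate origin and are
kept as single records — the D-loop (16030–570) is the motivating case.
A genome without sequence (`CircularGenome(length = 16569)`) supports
everything except motif scanning and sequence output.

# The synthetic-data generator

Because raw long-read data are large and external, the package ships a
generative simulator whose output has exactly the statistical structure
the analysis assumes. Per molecule:

1. each configured hotspot (kind `nick_heavy`, `nick_light` or `dsb`)
   fires independently with its per-molecule rate;
2. background nicks arrive per strand as a Poisson process with mean
   $L \times$ `backgroundNickRate` and uniform positions;
3. opposing-strand nicks closer than `nickToDsbDistance` (default 10 bp)
   collapse into a single DSB at the heavy-strand nick position,
   modelling spontaneous DSB formation from clustered SSBs;
4. optional S1 treatment (`s1Treat`) moves all nicks into the DSB set
   (idempotent, by construction);
5. a restriction cut is added at `eagIPosition` with probability
   `eagIEfficiency`; all DSBs plus the cut partition the circle into
   clockwise arcs, one fragment per arc. An uncut circle yields no
   fragment (circles are not sequenced); a single cut yields one
   full-length linear molecule;
6. size selection retains fragments of at least `sizeMin` bp (default
   3000; a fragment of exactly 3 kb is kept — "remove fragments
   < 3 kb" is read as a strict inequality);
7. nuclear background fragments are appended (expected share
   `nuclearFraction`), with log-normal lengths (default median 8 kb,
   $\sigma_{\log} = 0.5$) truncated at `sizeMin`, carrying lengths only.

Two conventions fix ambiguities the measurement itself does not
determine:

- **End convention.** A DSB at position $p$ separates $p$ from $p+1$:
  the left fragment's downstream end is $p$, the right fragment's
  upstream end is $p+1 \pmod L$. This makes the simulator's truth table
  exactly recoverable from fragment ends before size selection, and the
  profiling code uses the same convention.
- **Cut position.** The enzyme's exact cut site within its recognition
  window is not part of the downstream contract (ends near the site are
  excluded anyway); the simulator's default, position 2567, lies inside
  the excluded window 2550–2585 and is configurable.

All randomness flows from the single integer `seed`, with a documented
draw order (per-molecule hotspot/background draws, then the per-molecule
cut Bernoullis, then nuclear counts and lengths), so libraries are
byte-reproducible.

The generator emulates break placement, linearization, size selection
and library composition. It does **not** emulate base-level sequencing
error, chimeric reads, alignment ambiguity, or instrument length bias —
so green tests demonstrate correctness of the analysis on its stated
input contract (aligned fragment coordinates), not robustness to
upstream artifacts. The length-bias weighting (`lengthBiasWeights`,
`selectReferenceLibrary`) exists for real libraries where such bias is
present; it is off for simulator input, which has none.

# End profiling

`extractEnds` collects both termini of every mitochondrial fragment and
drops (counting them) ends inside the restriction-site exclusion
window, since those are artifacts of linearization, not breaks. Ends
are then tallied into bins anchored at position 1: bin $k$ covers
$[(k-1)w + 1,\, kw]$ clipped at $L$. At the default $w = 40$ and
$L = 16{,}569$ this gives 415 bins, the last covering 16,561–16,569
(width 9). The short final bin is kept rather than merged — the
simplest reproducible convention. One consequence: exact
rotation-equivariance of *binned* profiles holds only when $L$ is a
multiple of $w$; the rotation tests therefore use a 16,560-bp circle,
while per-position quantities are tested at 16,569.

Depth normalization divides bin counts by the mean sequencing depth
$\sum_i \mathrm{len}_i / L$ computed from the retained
(post-size-selection) mitochondrial fragments — what the sequencer
actually observed. Mito-only depth is used (total depth would couple
the normalization to the nuclear contamination level); this is a
documented, switchable choice in the sense that the depth value is an
explicit argument to `normalizeToDepth`.

Size distributions default to 500-bp classes from 0 to 20 kb plus an
overflow class, with "large fragments" meaning a lower class edge at or
above 10 kb; the grid is an explicit argument wherever it is consumed.

# Break calling

**Background subtraction.** The residual profile is
$r_k = f_k - \operatorname{median}\{f_{k-w'}, \ldots, f_{k+w'}\}$ with a
*circular* window (default half-width 25 bins, about 1 kb). A local
running median is the least-assumption background estimator: it is
robust against exactly the sharp peaks being sought, removes slow
coverage trends, and is location-invariant (adding a constant to the
profile leaves residuals unchanged — a tested property). The window
half-width is a parameter; halving or doubling it mainly changes how
wide a plateau can be before it starts absorbing into its own
background.

**Ranking.** `rankTopBins` removes bins overlapping excluded regions —
by default the D-loop and oriL, whose ends reflect replication
intermediates rather than damage — then sorts by residual descending
with ties broken by lower bin index, giving deterministic output
independent of input order and of any positive rescaling of the
residuals. The exclusion applies to ranking only, never to the profile
itself. Residuals are ranked on the S1 profile by default (it carries
SSB + DSB signal); `rankOn = "native"` ranks DSB-only ends instead.

**Differential clamping.** In expectation S1 ends are a superset of
native ends, so negative bin differences are sampling noise; they are
clamped to zero and counted in the `SSBProfile` diagnostics rather than
propagated as signed values.

**Break classes.** A called bin is labelled `SSB` when its differential
value exceeds twice its native value, `DSB` in the converse case, and
`mixed` otherwise. The factor 2 is a readability threshold for the
report, not an inference procedure, and is a parameter of
`classifyBreakBins`.

**Stalling sites.** `stallingSiteQuery` reads depth-normalized end
frequencies either at exact positions (given an end table and depth) or
at bin resolution (given a profile), recording which mode produced the
number. The default panel is the degradation stalling-site set
(3210, 5736, 5969 upstream; 9921, 14249 downstream). Note the end
convention: a DSB planted at $p$ is read out at $p+1$ for upstream
ends.

# Motif annotation

GC stretches are maximal runs of `{G, C}` of at least `minRun` bases
(default 6 — "long" is not quantified by the biology, so the threshold
is a reported parameter). G-quadruplex motifs use the standard
four-tract rule `G{3,}(N{1,7}G{3,}){3}` on the heavy strand and on the
reverse complement (reported in heavy-strand coordinates as `light`).
Both scans handle the circle by scanning the doubled sequence and
keeping matches that start within the first copy; G4 matching is
leftmost, non-overlapping, with lazy quantifiers so a circular match
never exceeds one circumference. Exact motif extents under a
backtracking regex are convention-laden; the package pins the
convention and verifies it against an independent recursive matcher.

`annotateHotspots` flags calls with a motif within `flank` bp by
circular arc distance (overlap = 0). `rotationAssociationTest` gives a
quantitative co-localization check: the motif set is rotated by uniform
random offsets — preserving motif clustering, hence conservative
compared to independent repositioning — and
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$, never exactly
zero by the add-one rule.

# Kinetics

**Decay.** `fitExponential` fits $\ln y = \ln N_0 - kt$ by least
squares: exact on noiseless exponentials, and the natural estimator for
band intensities normalized to a 0-h reference. Series containing zeros
route to a direct nonlinear fit (`method = "nls"`). Half-life is
$\ln 2 / k$, infinite for $k \le 0$.

**Dilution decomposition.** An apparent decay rate confounds
degradation with dilution by newly synthesized genomes:
$k_{\mathrm{deg}} = k_{\mathrm{app}} - \ln 2 / t_{\mathrm{double}}$.
When $k_{\mathrm{deg}} \le 0$ the observed decay is fully explained by
division and the result is flagged dilution-dominated;
$t_{\mathrm{double}} = \infty$ recovers the apparent half-life (a tested
limit). For example, an apparent 26-h half-life at a 30-h doubling time
leaves a degradation half-life of 195 h, whereas an apparent 12-h
half-life leaves 20 h.

**Chapman qPCR curves.** Amplification traces are fitted with
$y = y_0 + a(1 - e^{-bx})^c$ and the quantification cycle defined at
the inflection, $Ct = \ln(c)/b$ (the root of the second derivative —
verified numerically). The four-parameter form includes a baseline
offset $y_0$; the inflection of the shape term does not depend on
$y_0$ or $a$, so this choice affects fit quality, not the Ct
definition. Fitting uses Levenberg–Marquardt over a multi-start grid
($y_0 = \min y$, $a = \operatorname{range} y$, $b$ over 0.05–1 per
cycle, $c$ over 1.5–100), best residual sum of squares wins; fits with
$c$ at the $c \le 1$ boundary degenerate to a saturating exponential
with no interior inflection and return `NA` for Ct with a flag.

**Copy number.** $\mathrm{copies} = 2 \cdot
\mathrm{eff}^{Ct_{\mathrm{nuc}} - Ct_{\mathrm{mito}}}$, the factor 2
counting both alleles of the diploid single-copy nuclear reference
locus. Efficiency defaults to 2 (perfect doubling) since no efficiency
correction is applied; it is monotone in $\Delta Ct$ and exactly 2 at
$\Delta Ct = 0$ for any efficiency.

**Depletion/repopulation.** Under replication arrest the depletion
phase ($t \le$ switch) is fitted as an exponential; recovery is
summarized as the first post-switch time at which the signal reaches a
stated fraction (default 0.9) of the pre-treatment baseline, measured
from the switch. With no post-switch samples, recovery is "not
observed". The two phases are deliberately reported separately rather
than as a joint model — the release of arrest is a step change in the
system, not a parameter to estimate.

# Verification strategy and problem sizes

Every nontrivial primitive is checked against an independent
brute-force oracle built in the test helpers: stepwise walks on the
circle for distance and membership, per-position scans for binning, a
tripled-vector median for the circular running median, a per-position
walking scan for GC runs, and a recursive backtracking matcher for the
G4 rule (100 random instances each, at most 200 elements). Conservation
laws (fragment lengths summing to $L$; retained + excluded ends
equalling twice the fragment count; bin sums equalling end counts) run
over 100 randomized simulations. Pipeline-level recovery uses a
5,000-molecule paired experiment with three nick-only hotspots and one
DSB hotspot at rate 0.05 over a $10^{-5}$ per-base background — rates
high enough that recovery is expected with large margin, small enough
that the background is realistic — and checks that each hotspot
surfaces in the correct library and nowhere else. Decay recovery uses
500 replicates of 6-point series under $\sigma = 0.2$ multiplicative
log-normal noise. These sizes keep the full suite under a minute while
leaving order-of-magnitude margins on every stochastic assertion.

# Known limitations

- Alignment is consumed, not performed: inputs are fragment coordinate
  tables (simulator TSV, BED, or reduced SAM/BAM coordinates prepared
  upstream).
- No formal peak-calling FDR across bins — the method ranks residuals,
  mirroring how the measurement is used; the rotation-permutation test
  covers motif association only.
- BED input cannot represent origin-spanning fragments; use the
  fragment TSV for those.
- The nuclear compartment is modelled as fragment-length bookkeeping
  only (no nuclear genome model).
- Binned rotation-equivariance is exact only for $L$ a multiple of the
  bin width (see above); per-position operations are exact on any $L$.
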