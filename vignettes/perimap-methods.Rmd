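---
title: "Models and methods behind perimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimap)
```

perimap quantifies how chromosomes are folded around yeast pericentromeres
from two kinds of sequencing experiments: spike-in calibrated ChIP-seq of
cohesin subunits, and Hi-C contact maps of prophase-arrested meiotic cells.
This vignette explains the models the package implements, the tunable
parameters and their defaults, what the synthetic data generator does and
does not emulate, and the numerical choices made where the underlying
procedures left them open.

## Spike-in calibrated ChIP-seq

A calibrated ChIP-seq sample mixes chromatin of the experimental genome
(*S. cerevisiae*-like, subscript `x`) with a fixed spike-in of a calibration
genome (*S. pombe*-like, subscript `c`). Reads are assigned per genome in
both the input (`W`) and the immunoprecipitate (`IP`), giving four totals
from which the occupancy ratio is computed:

$$OR = \frac{W_c \cdot IP_x}{W_x \cdot IP_c}.$$

`occupancyRatio()` implements exactly this. The calibrated per-bin track is

$$\text{calibrated}_b = \text{coverage}_b \cdot \frac{OR}{IP_x}
 = \text{coverage}_b \cdot \frac{W_c}{W_x \cdot IP_c},$$

implemented in `calibrateTrack()`. The division by `IPx` is a design
choice: the source material for the method states only that positions are
"normalized using the OR" without naming the denominator. Dividing by the
sample's own IP total makes the track invariant to IP sequencing depth
(which scales coverage, `IPx` and `IPc` together) while leaving it
proportional to true occupancy — which is the purpose of spike-in
calibration. This is the single normalization convention used throughout.
For antibodies with no usable spike-in signal, `calibrateTrack(sample, or =
<constant>)` runs the same normalization under a stated constant instead.

`featureMetaprofile()` averages the calibrated signal across a feature
class at 50 bp offsets within ±3 kb of the feature midpoints (both
configurable; the track must be at least as fine as the step — coarser
tracks are rejected rather than silently interpolated). Features on the
right arm are flipped when `orient = TRUE`, so the centromere-proximal side
of a pericentromere border always maps to the same profile side. Flipped
features sample bins under the right-closed convention, so a midpoint
sitting exactly on a bin edge still maps onto the mirror image of the bin
its unflipped twin uses. The uncertainty band is the pointwise standard
error across features with a 95% confidence interval taken as mean ± 1.96
SE (normal approximation; the method's source does not state its interval
construction). Missing bins and window parts truncated at chromosome ends
are dropped from the mean with the per-offset `n` tracked.

ChIP-qPCR enrichment uses the dilution-corrected threshold-cycle
difference

$$\Delta C_t = C_t^{ChIP} - \left(C_t^{Input} - \log_E(\text{dilution})\right),
\qquad \text{enrichment} = E^{-\Delta C_t},$$

with `E` the primer amplification factor per cycle. The printed formula in
the method's source is typographically garbled (operators missing); the
form above is the standard dilution-corrected one and is pinned down by a
round-trip test against `simulateQpcr()`, which inverts it exactly at zero
noise.

## Contact matrices and balancing

`binPairs()` assigns each valid cis pair to bins `floor(pos/resolution)`
(0-based, half-open; the last partial bin is kept) and accumulates a
symmetric per-chromosome count matrix; trans pairs are retained only as a
total. `iceBalance()` performs iterative correction: bins with zero
marginal count, plus bins in the lowest 2% of nonzero marginals (the
standard pre-filter where the upstream toolchain's thresholds are not
published; configurable), are masked, and per-bin weights are scaled until
the coefficient of variation of the balanced marginals falls below 1e-5
(at most 200 iterations). Weights are normalized so the mean balanced
marginal over valid bins is 1 — an arbitrary but harmless scale, since
every downstream readout is a ratio or shape. Raw counts are never
modified; masked bins surface as NA ("white stripes") in every window
extracted with `cisSubmatrix()`. Each chromosome is balanced on its own
cis matrix, matching the cis-only scope of the analyses.

## P(s), slope, and loop size

`contactProbability()` pools balanced pixel values into log-spaced
distance bins (16 per decade; representatives are pixel-weighted geometric
means) across chromosomes, excluding pixels whose bins lie on opposite
sides of — or inside — the centromere interval, so that only same-arm
contacts contribute. P(s) is reported as the mean balanced value per valid
pixel, with no further normalization: all downstream comparisons are
shape-based.

`slopeCurve()` estimates d log10 P / d log10 s as the least-squares slope
of log10 P against log10 s in a centered window of 3 bins. A
moving-average of log10 P followed by finite differences — the textbook
recipe — is biased wherever the log-bin spacing is uneven (averaging a
linear function at uneven abscissae displaces it); the windowed regression
is exact on a power law regardless of spacing and averages noise
comparably. The window default of 3 keeps the slope maximum close to the
enrichment it reflects; wider windows smear the loop signature and push
the maximum further down its rising flank.

`loopSizeEstimate()` returns the distance at the maximum of the slope
curve inside a search range (default 3–200 kb), the estimator used on the
real maps: contacts enriched near the typical anchor spacing lift the
slope just below that spacing, so the maximum tracks the average loop
size. Two properties of this estimator are worth stating plainly:

* It carries a systematic low bias of one to two log bins (roughly
  15–25%), because the slope maximum of a background-plus-bump curve sits
  on the bump's rising flank, not at its crest. The recovery tests budget for
  this; the ~10/20/40 kb scale readouts it supports are themselves stated
  only to "~" precision.
* On a pure power-law map the slope is constant and the maximum is
  noise. The estimate is therefore accompanied by a `noPeak` flag, raised
  when the in-range slope maximum exceeds the in-range median by less
  than 0.05 slope units — comfortably above the per-bin noise of a deeply
  sequenced map and well below the weakest loop signature simulated here.

## Pileups and scores

`snipPileup()` averages balanced windows centered on features, in linear
space; log10 belongs to presentation only (the mean of logs is not the log
of the mean). Centromeres, having no orientation, use `mode = "mirrored"`:
each window is symmetrized before accumulation, which makes the pileup
bitwise-exactly symmetric under double-axis reversal. Borders use `mode =
"oriented"`: right-arm windows are axis-reversed so the arm flank maps to
the upper-left and the centromere flank to the lower-right corner. Default
flanks are 100 kb for centromere pileups ("200 kb surrounding") and 25 kb
for border pileups, both configurable. `ratioPileup()` computes per-pixel
log2 differences as `log2(A) - log2(B)`, so swapping the inputs negates
the map bitwise.

The insulation, dot and stripe statistics are quantifications defined in
this package — the phenomena they measure are shown in the source material
only as images — and they are validated against the generator's dials
rather than against any published number:

* `insulationScore()` is log2(mean crossing contact / mean same-side
  contact) in a ±20 kb window, combining per-distance means with equal
  weight per distance in both classes. The distance matching matters: the
  two classes have different distance mixes, and pooling raw pixels lets
  the decay curve masquerade as insulation. With matching, a boundary that
  transmits a fraction m of crossing contacts scores exactly log2 m on its
  expectation map.
* `dotScore()` divides the mean of the central 3×3 pixels of a pileup by
  the mean of flanking strips at the same genomic-separation band
  (Chebyshev radius 4–9, separation offset within the center's). Matching
  the separation band keeps the distance decay out of the ratio. On dot
  pileups built with `anchorPairPileup()` the score grows monotonically
  with the generator's dot strength but stays below it, since the 3×3
  center averages over the dot's Gaussian shoulder.
* `stripeProfile()` reads the balanced matrix along a 3-bin band through
  an anchor, separately per direction, so one-sided enrichment ("stripes")
  appears as a left/right asymmetry against the shared decay background.

Balancing interacts with these scores: on a small genome, ICE partially
compensates a strong boundary (the boundary bins' depleted marginals earn
larger weights), compressing sampled-map insulation scores toward zero
while preserving their ordering. Accuracy claims are therefore stated on
expectation maps with unit weights (`unitBalanced()`), monotonicity claims
on sampled, ICE-balanced maps.

## The synthetic data generator

`simulateContactMap()` draws Poisson counts around the expectation

$$E_{ij} = k \; d_{ij}^{-\alpha}\; m^{\#\text{boundaries between } i,j}
 \;\text{dot}(i,j)\;\text{stripe}(i,j),$$

where `d` is the bin-midpoint separation (resolution/2 on the diagonal), α
is the decay exponent, m the boundary transmission multiplier, and k
scales the total upper-triangle expectation exactly to the requested
depth. Loop anchors are laid down sequentially with Gamma-distributed gaps
of mean L and coefficient of variation 0.1 (clipped below at twice the
resolution); consecutive anchor pairs carry a Gaussian enrichment blob (σ =
1 bin, fold `dotStrength`). The near-regular spacing is deliberate: a
slope-maximum estimator can only recover L if the dot-distance
distribution is peaked near L. Memoryless (exponential) gaps place most
dots well below L — their distance density is maximal at the clip — which
turns the loop signature into a slope *dip* and leaves the slope maximum
pinned at the search boundary. A CV of 0.1 matches the visual regularity
of prophase loop arrays well enough for the estimator's purpose without
simulating extrusion dynamics. The optional stripe extends one-sided
enrichment from each anchor toward higher coordinates up to the next
anchor (off by default).

`simulateChipReads()` models the IP library as a read competition: a fixed
budget of `depthIPx + depthIPc` reads is split between experimental and
calibration material in proportion to their masses, with the calibration
mass anchored so an occupancy-free sample yields the stated depths
exactly. This matters: holding the calibration read count fixed while
experimental occupancy varies would bias calibrated ratios by the IP
material share and would remove precisely the effect the occupancy ratio
corrects. Per-bin material is a flat background (default 1 unit) plus
Gaussian peaks (σ = 100 bp) of height occupancy × IP efficiency at each
feature; `IPx` is the realized coverage sum, keeping track and total
consistent by construction.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: restriction-fragment geometry and
ligation artifacts near the diagonal, trans contacts, copy-number and
replication structure, distance-dependent polymer physics beyond a single
power law, negative-binomial overdispersion (counts are Poisson so that
the oracles stay closed-form), mappability structure in ChIP coverage, and
any sequence-level effect. The generator's role is to provide ground truth
for the estimators' *algebra and geometry*, not biological realism.

## Problem sizes and determinism

The shipped tests and the acceptance script run on genomes of four 700 kb
chromosomes at 1 kb resolution with 5×10⁶ cis contacts per map (5×10⁷ for
the loop-free reference map, where per-bin slope noise must sit well below
the decay exponent), ten seeds per condition — the scale at which the
slope estimator's sampling error is comfortably inside the tolerances
while a full multi-condition run stays within minutes on one CPU. Every
stochastic stage takes an explicit integer seed and is a pure function of
its arguments; reruns of `runPipeline()` with the same config are
byte-identical for all deterministic outputs. Single-threaded reduction
order is fixed; nothing in the package spawns threads.

## Known limitations

* The loop-size estimator inherits the flank bias discussed above plus
  log-bin quantization; both are inside the "~" precision of the scale
  ladder it reproduces, but it should not be read as an unbiased point
  estimator.
* Insulation scores on ICE-balanced maps are compressed toward zero
  relative to the generative multiplier; comparisons should stay within
  one balancing convention.
* Cross-centromere exclusion classifies bins by their midpoints; at
  resolutions coarser than the centromere interval a single bin may
  straddle it and be dropped from both arms.
* The pipeline holds per-chromosome dense matrices in memory; it is sized
  for yeast-scale genomes at ≥1 kb bins, not mammalian maps.
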