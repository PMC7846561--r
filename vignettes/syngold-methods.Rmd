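---
title: "SynGold: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SynGold: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynGold)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. The companion README shows the user-facing
workflow; here the emphasis is on the model assumptions, the
conventions that resolve ambiguities, and the numerical decisions a
maintainer would want written down.

## The data model

An annotated synapse section (`ProfileAnnotation`) stores membrane
polylines (AZ and PSD traces) and point sets (gold particles, docked
vesicles, exocytic pits) in Cartesian nanometres with an arbitrary
per-profile origin. Depth is never stored: it is derived as
`sectionIndex * sectionThicknessNm`, which encodes the assumption that
all sections of a stack have equal thickness. Stacks are assumed
laterally pre-aligned; an optional per-profile `(dx, dy)` offset
(default zero) absorbs any residual alignment, and the middle section's
trace centre anchors the 3D frame. JSON is the canonical on-disk format
because polylines need nesting; the CSV export is intentionally lossy
(one point per row, no traces).

## Distance conventions

**2D.** A particle is projected onto the membrane trace and located by
*arc length* from the trace centre, normalized by the half-width
(half the total arc length). Arc length, not chord distance, is the
default because the traces are curved membranes and the half-width is
itself an arc quantity; a `mode = "chord"` switch exists for
sensitivity analysis. The 0 = centre / 1 = edge convention fixes the
direction of the normalization (distance *from the centre* divided by
the half-width). Points that project beyond a trace terminus keep
`normalized > 1` and carry a `beyond_edge` flag rather than being
clamped — exclusion is a pooling decision, not a measurement decision
(`poolDistributions(excludeBeyondEdge = )`, default include).

**3D.** The size of a reconstructed PSD is summarized as the
equivalent-circle radius $R_{eq}=\sqrt{A/\pi}$ with
$A=\sum_s L_s\,t$ (trace length times thickness). Whether a maximum
extent would serve equally is genuinely open; the equivalent circle is
the default because the fractional-area correction already assumes a
circular PSD, making the two conventions consistent with each other.
The fractional-area transform `normalized^2` is exact algebra, not an
estimate, and is asserted to machine precision in the tests.

## The synthetic generator as a forward model

The generator exists so that every downstream stage can be tested
against known ground truth. It emulates, in order:

1. **Placement** on a disc-shaped PSD of radius 150 nm (AZ congruent by
   default). Laws are parameterized on fractional area $u=(r/R)^2$, so
   uniform is exactly $\mathrm{Beta}(1,1)$, edge bias
   $\mathrm{Beta}(a,1)$, centre bias $\mathrm{Beta}(1,b)$. The
   clustered law draws centroids on a 0.7 R disc and scatters Gaussian
   clusters, clamped to the disc. An optional minimum centroid
   separation (`clusterMinSepNm`) exists because two independently
   drawn centroids frequently land close enough to merge into one
   apparent cluster, which no cluster-number method can be expected to
   resolve; the two-cluster preset uses 120 nm, the scale of distinct
   receptor nanodomains.
2. **Labeling**: each receptor becomes a gold particle with probability
   0.5 (the working estimate of labeling efficiency), plus Poisson
   background at 0.03 per profile placed on the annulus just outside
   the PSD.
3. **Random sectioning**: a random chord direction and a random slab
   phase cut the disc into profiles of fixed thickness (40 nm for TEM
   presets, 20 nm for block-face ones). Each slab's trace is the chord
   at its centre; a particle's in-profile position is its signed
   distance along the chord. Because a uniform surface density
   restricted to a slab is uniform along the chord, pooled profile data
   recover the underlying radial law — this is the property that makes
   single-section data informative, and the test suite verifies it by
   Monte Carlo. The slab grid holds exactly $\lceil 2R/t \rceil$ slabs
   with the disc at a uniform random phase inside it; a fully free
   grid can touch one extra sliver slab at each rim, which would
   occasionally produce an extra near-empty profile without changing
   any distributional property.

Per-profile docked-vesicle and pit counts arise from 3D placement at
rates of 1.9 and 0.28 expected points per profile, not from
independent 2D draws, so their per-profile statistics inherit the slab
geometry. The pit presets' Beta shapes — $\mathrm{Beta}(1, 1.55)$ for
the 5-ms-like condition and $\mathrm{Beta}(1, 13.5)$ for the
11-ms-like one — are numerical calibrations of this forward model to
pooled 2D medians of about 0.40 and 0.13; they are package choices,
not measured constants.

What the generator does *not* emulate: electron-optical artifacts,
annotation/segmentation error, size variation across synapses (the
disc radius is a single configured value, so SSD-versus-area
regressions on generated cohorts are degenerate by construction and
the pipeline skips them), and any correlation between receptor and pit
positions. Passing tests therefore demonstrate correctness of the
analysis chain under its stated assumptions, not robustness to every
property of real micrographs.

## Cluster analysis

`kmeansLloyd()` is plain Lloyd iteration — uniform-random initial
centroids from the data (deliberately not k-means++, keeping the
algorithm exactly the named one), best of `nInit = 10` restarts, empty
clusters re-seeded to the farthest point. The SSD curve inherits each
k's warm start from the best (k−1) solution plus the worst-fit point,
which makes the curve non-increasing by construction.

The knee of the curve is the point of maximum perpendicular distance
to the end-to-end chord after min-max normalization of both axes, ties
broken toward smaller k. One subtlety deserves emphasis: this rule
*cannot* return k = 1 on any strictly convex decaying curve, yet an
unclustered synapse must be reported as one cluster. `clusterAnalysis()`
therefore applies a prominence guard: if the maximum normalized chord
distance is below `kneeThreshold = 0.5`, no knee is declared and k = 1
is reported. The threshold sits in the measured gap between the smooth
power-law-like decay of unclustered point sets (prominence roughly
0.32–0.46 across simulated synapses) and the sharp elbows of planted
clusters (roughly 0.51–0.62); it is applied identically to observed
data and to null maps. Synapses with fewer than four particles skip
knee selection entirely and report k = 1, since meaningful clusters
start at about four particles.

The randomization null re-places the observed number of particles
uniformly over the reconstructed PSD surface (sections weighted by
trace length × thickness, uniform along each trace, depth at the
section centre) and re-runs the entire selection on each of 50 maps,
each map choosing its own k. Letting the null choose its own k keeps
the null self-consistent — the quantity compared is "SSD at the
selected k", and the selection is part of the procedure; a
`nullK = "data"` switch fixes the data's k instead.

## Inferential battery

The one-sample Wilcoxon signed-rank test against the theoretical
median 0.5 drops values exactly at the null median (Wilcoxon's
convention) and uses the exact null for n ≤ 25 without ties, otherwise
the tie-corrected normal approximation with continuity correction; the
two-sample Mann–Whitney switches branches at min(n, m) = 8. Both
branches agree to better than 0.01 in p at the crossover, and their
type-I error at α = 0.05 is verified to lie in [0.035, 0.065] by
simulation. The two-sample Kolmogorov–Smirnov test uses the asymptotic
Kolmogorov distribution. Dunn's post-hoc test is computed from pooled
ranks with tie correction and Bonferroni-scaled pairwise p-values,
matching the global use of Bonferroni elsewhere; the D'Agostino–Pearson
omnibus test combines the standard skewness and kurtosis z-transforms
and refuses n < 20 where those approximations break down. Bootstrap
CIs for medians are percentile intervals with B = 10,000 by default and
an explicit seed, so summary tables are reproducible.

## Receptor simulation

The geometry is deliberately reduced: an analytic disc cleft replaces
any meshed neuropil, with clearance by surrounding tissue collapsed
into a single first-order time constant (default 1 ms). The transient
$C(r,t)=\frac{N}{h4\pi Dt}e^{-r^2/4Dt}e^{-t/\tau}$ preserves the two
features the conclusions rest on — the steep distance dependence and
the sub-millisecond time course — and is exactly mass-conserving when
clearance is off, which the tests integrate numerically. Defaults:
2000 molecules per vesicle, 20 nm cleft height, D = 0.3 µm²/ms.

Receptor schemes are small Markov models with rate laws restricted to
constant, ligand-proportional, and exponential-in-voltage (Mg block and
unblock). The published rate constants behind comparable models are
not reproduced here; the shipped defaults are representative values
calibrated once against the behavioural invariants the package
asserts:

* AMPA (`ampaScheme()`): two binding steps (0.009 /µM/ms per site),
  fast gating, desensitization from the doubly bound state recovering
  at 0.02 /ms — slow enough that paired releases within ~15 ms depress
  the second response, and binding weak enough that a release 100 nm
  away reduces the peak open count by a mid-band fraction of the
  direct-release response.
* NMDA (`nmdaScheme()`): slow unbinding (0.06 /ms per site) so
  receptors stay bound across the EPSP time course, slow gating, and a
  *ligand-proportional* desensitization rate (0.003 /µM/ms from the
  doubly bound state). The ligand proportionality matters: with a
  site-independent EPSP template, the only mechanism that can
  penalize two releases onto the same cluster relative to one distant
  plus one direct release is that a strong direct transient
  desensitizes already-bound receptors. This choice is what produces
  the ordering "double release at the NMDA cluster < synchronous at
  AMPA followed by asynchronous at NMDA" while keeping the two mixed
  orders within 10% of each other.
* Mg block (`mgBlockParams()`): non-trapping by default (block only
  from open, unblock back to open; a trapping variant sits behind a
  flag), 1 mM Mg, block/unblock at 0 mV of 1 /ms/mM and 3 /ms, e-fold
  slopes 17 and 20 mV. The equilibrium blocked fraction is strictly
  decreasing in voltage by construction.

The EPSP template is piecewise monotone: a cubic smoothstep rise from
(0, 0) to the (4 ms, +25 mV) peak and a Fritsch–Carlson monotone cubic
through (8, 50/3), (10, 2), (15, 0). A single spline through all five
knots was rejected because it overshoots the peak; building the limb
segments separately pins the peak at exactly +25 mV and the 8-ms value
at exactly 2/3 of it. Events sum linearly, capped at +45 mV, the
depolarization level reached by two near-coincident releases.

### Integration

The master equation is integrated by classic RK4 on a fixed grid
(default 1 µs over 250 ms) with ligand and voltage sampled at half
steps. Right after a release the binding rate at the release site
briefly approaches the RK4 stability limit, and two coincident releases
exceed it; the integrator therefore sub-steps automatically whenever
the summed outflux rate times dt exceeds 0.5, interpolating the inputs
linearly within the step. Occupancies are renormalized every step with
observed drift far below 10⁻⁶, and leaving [−10⁻⁶, 1+10⁻⁶] aborts with
advice to reduce dt rather than silently clamping. The stochastic mode
runs independent per-receptor chains by fixed-step thinning with the
same sub-stepping rule (per-substep jump probability ≤ 0.2) and draws
from R's RNG so `set.seed()` governs it; mean-field and stochastic
means agree within sampling error at the default 48 trials.

Concentration at a release site is evaluated from t = 1 µs — the first
integrator sample — because the point-source solution diverges at
t = 0; the time integral of the transient is finite, so this floor
only regularizes the first step.

## Seeds and reproducibility

Every stochastic entry point takes a seed; internal streams are split
from it (`sample.int` under the master seed), and all seeded code paths
restore the caller's RNG state on exit, so library calls never perturb
a user's session stream. The pipeline hashes its configuration into a
manifest and skips stages whose hash is unchanged; identical configs
produce byte-identical outputs.

## Problem sizes in the shipped checks

The package's own test suite runs at deliberately modest sizes chosen
to make each check informative rather than exhaustive: placement-law
checks at 10⁴–10⁵ draws, the uniform-pipeline median at three seeds of
300 synapses (~6,000 pooled particles per seed, where the ±0.02
acceptance band is several standard errors wide), k-means oracle
equivalence on 200 instances of up to 8 points (exhaustive enumeration
is the oracle; Lloyd runs 30 restarts there because the property
quantifies over the global optimum), knee recovery on 100 synapses per
preset, type-I error at 1,000 replicates, and the scenario grid at the
full 1 µs step. The full suite runs in well under a minute of compute
plus the grid's few tens of seconds.

## Known limitations

* The analysis assumes the AZ/PSD is topologically a disc and the
  trace centre is a meaningful origin; horseshoe-shaped or perforated
  PSDs violate both.
* The 3D lateral frame is one-dimensional along each section's trace
  (plus the per-profile offset); curvature of the synapse across
  sections is not modelled.
* The simulator's EPSP is a template triggered per release event,
  independent of which receptors actually open; feedback from AMPA
  current to voltage is outside scope, and the N-N versus A-N ordering
  consequently rests on ligand-dependent desensitization rather than on
  a smaller AMPA-driven EPSP.
* Kinetic defaults are representative, not fitted; absolute AUC values
  have no quantitative claim attached, only the orderings and
  monotonicities the tests assert.
* The generator's fixed disc radius makes synapse-size regressions on
  synthetic cohorts degenerate; supply per-synapse areas from real
  reconstructions to use `regressSsdVsSize()` meaningfully.
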