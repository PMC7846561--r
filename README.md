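# SynGold

Spatial statistics of immunogold-labeled synaptic receptors, and a
desk-scale simulator of AMPA/NMDA receptor activation by patterned
glutamate release.

## What problem this addresses

Electron microscopy of labeled synapses produces point annotations:
gold particles marking surface receptors, docked synaptic vesicles, and
exocytic pits, all lying along traced active-zone (AZ) and postsynaptic
density (PSD) membranes, in single 2D sections or serial-section 3D
stacks. Two questions recur in this kind of data:

1. **Where are things within the synapse?** Are receptors or fusion
   sites biased toward the centre or the edge of the PSD/AZ, and do
   they form clusters beyond what chance placement predicts?
2. **What do those positions mean for signalling?** How much does
   receptor activation change when glutamate is released directly over
   a receptor cluster versus ~100 nm away, synchronously versus a few
   milliseconds later, at rest versus during an EPSP?

SynGold is aimed at electron microscopists and computational
neuroscientists who need a tested, reproducible implementation of this
analysis chain, including a synthetic-data generator with known ground
truth so every stage can be validated without access to micrographs.

## The statistics at the core

**Normalized lateral distance (2D).** For a particle \(p\) and a
membrane trace of arc length \(L\), project \(p\) onto the trace and
measure the arc distance \(d\) from the projection to the trace centre
(the point at arc \(L/2\)). The normalized location is
\(\hat r = d / (L/2)\): 0 at the centre, 1 exactly at the edge. Under a
uniform surface distribution on a circular PSD, pooled \(\hat r\) from
randomly sectioned profiles has median 0.5, so bias is tested with a
one-sample two-tailed Wilcoxon signed-rank test against 0.5.

**3D distance and fractional area.** In a serial reconstruction the
distance to the synapse centre is
\(\sqrt{d_{lat}^2 + (\Delta s \cdot t)^2}\) (Pythagoras with section
thickness \(t\)), normalized by the equivalent-circle radius
\(R_{eq} = \sqrt{A/\pi}\) of the reconstructed PSD. Squaring the
normalized distance gives the *fractional area* \(\hat r^2\) of the
bounded circle, which turns a uniform surface distribution into a
uniform distribution on [0, 1]; a particle at \(\hat r = 0.5\) has
fractional area 0.25 — equidistant between centre and edge.

**Cluster analysis.** Per synapse, K-means (Lloyd's algorithm) is run
for k = 1..N gold particles; the within-cluster sum of squared
distances SSD(k) is non-increasing, and the cluster number is the
knee of this curve (maximum distance to the chord on min-max-normalized
axes, with a prominence guard so unclustered synapses report one
cluster). The observed SSD is compared against 50 maps with particle
positions randomized uniformly over the reconstructed PSD surface, and
SSD is regressed on PSD area for observed and randomized series.

**Receptor simulation.** Glutamate from a single vesicle spreads in the
cleft as a 2D point-source transient
\(C(r,t) = \frac{N_{glu}}{h\,4\pi D t} e^{-r^2/4Dt}\, e^{-t/\tau}\),
driving Markov kinetic schemes for AMPA and NMDA receptors placed as
clusters 100 nm apart (~20 and ~15 receptors). NMDA receptors carry a
Woodhull-style voltage-dependent Mg²⁺ block
(\(k_{block} \propto e^{-V/17\,\mathrm{mV}}\),
\(k_{unblock} \propto e^{+V/20\,\mathrm{mV}}\)); a receptor conducts
only when glutamate-bound *and* unblocked. Voltage is clamped or
coupled to a single-release EPSP template (peak +25 mV at 4 ms, 2/3 of
peak at 8 ms, back to rest by 15 ms; linear summation capped at
+45 mV). Mean-field RK4 integration at a 1 µs step is the default; a
stochastic per-receptor mode (48 trials) estimates variability.

## Worked example

```r
library(SynGold)

## synthesize 40 synapses with one centre-leaning NMDA-like receptor
## cluster each, 20-nm sections, 50% labeling efficiency
gen <- generateDataset(presetConfig("NMDA_like", nSynapses = 40, seed = 11))
gen$dataset
#> GoldDataset: 600 profiles from 40 synapses
#>   provenance: generator, seed, law, nSynapses

## 2D normalized distances of every gold particle, pooled
d2 <- do.call(rbind, lapply(profiles(gen$dataset), function(p) {
  if (!nrow(gold(p))) return(NULL)
  normalizedDistance2D(gold(p), psdTrace(p))
}))
poolDistributions(d2, B = 2000, seed = 1)$summary
#>   group   n    median     ci_lo     ci_hi
#> 1   all 443 0.2160766 0.1960608 0.2449161

wilcoxonOneSample(d2$normalized)
#> Wilcoxon signed rank: statistic = 1.059e+04, p = 1.925e-46 (n = 443)

## per-synapse cluster analysis with a 50-map randomization null
recs <- reconstructSynapses(gen$dataset)
clusterAnalysis(recs[[1]], nMaps = 50, seed = 1)
#> ClusterResult syn0001: N = 9, k_opt = 1, SSD = 7297.2 nm^2
#>   randomized-null mean SSD = 86990.5 nm^2
```

The pooled median of 0.22 (95% bootstrap CI 0.20–0.24) sits well below
the uniform-placement value 0.5, and the Wilcoxon test rejects
uniformity — the generator planted a central cluster, and the analysis
recovers it. The cluster analysis picks one cluster whose SSD is an
order of magnitude below the uniform-null mean. Releasing glutamate
over the two receptor clusters is simulated with:

```r
sc <- Scenario(data.frame(t_ms = c(1, 6),
                          site = c("AMPA_cluster", "NMDA_cluster")),
               voltageMode = "epsp_coupled", durationMs = 250)
simulateScenario(sc)
#> SimResult:
#>   AMPA: peak 6.39 open at 1.19 ms, AUC 9.1 count*ms
#>   NMDA: peak 0.29 open at 9.31 ms, AUC 3.5 count*ms
```

The AMPA cluster responds fast and strongly to the release above it;
NMDA receptors open later and sparsely, gated by relief of the Mg²⁺
block during the summed EPSP. `scenarioGrid()` crosses release
patterns (A-N, N-A, N-N, A-A), inter-release delays (0–50 ms) and
voltage protocols into a tidy AUC table, and `runPipeline()` drives
generate → metrics → cluster → stats → simulate from one config.

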