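# envshift

Analysis pipeline for extracellular recordings collected under an **A-B-A'
design**: a baseline foraging session, a middle session in which the
environment is manipulated (an object inserted, the arena rotated, reshaped,
expanded, or its walls removed), and a return to the baseline configuration.
The scientific question is whether single neurons carry a *rate code for
environmental change* — a systematic shift of mean firing rate (MFR) that
appears in the manipulation session and reverses when the environment is
restored — and whether such shifts are distinct from running-speed
modulation and from slow population-level drift.

The package is written for systems-neuroscience users with tracking data
(30 Hz x/y positions) and sorted spike trains per cell, organized as
pre / manipulation / post session triplets. Because such datasets are rarely
public, the package ships a calibrated simulator (foraging trajectories +
inhomogeneous-Poisson spikes with known ground truth) so the entire pipeline
is testable end to end.

## What it computes

**MFR-change classification.** Each session is truncated to a common 765 s
window and cut into ten blocks of 76.5 s; the block MFRs form three groups
of ten. Cells are tested with a Kruskal-Wallis omnibus over the three
groups, followed by Scheffé-type pairwise comparisons on pooled ranks
(family-wise p for pair *(i, j)*: `P(chi²_{k-1} > t²)` with
`t = (R̄_i − R̄_j) / sqrt((N(N+1)/12 − T)(1/n_i + 1/n_j))`, tie adjustment
`T`). A cell is labeled *increase* (*decrease*) only when the manipulation
session differs from **both** flanking sessions at α = 0.05 with a
consistent sign of `Δ = MFR_manip − mean(MFR_pre, MFR_post)`.

**Speed tuning.** Instantaneous speed from 30 Hz finite differences;
occupancy-normalized tuning curves over 25 bins spanning 5–55 cm/s; a
uniform-vs-linear F-test `F = (RSS₀ − RSS₁) / (RSS₁/(n−2))` with
occupancy (inverse-variance) weights; a cell is speed-sensitive when
p < 0.05 in any of the three sessions. Display curves (0–60 cm/s, 2.5 cm/s
bins, sessions merged) feed shape categories and split-half stability.

**Spatial ratemaps.** 3 cm bins, rate = spikes / dwell time, unvisited bins
masked, Gaussian smoothing with masked renormalization (7 cm kernel), and
cross-session display normalization to the pooled 95th percentile.

**Population-vector correlations.** The whole-session MFR vector over the
full cell roster is Pearson-correlated with every 400 ms binned rate vector
(1912 complete bins per 765 s session), pooled into same-type and
cross-type distributions and compared with Kruskal-Wallis + Scheffé
post hocs.

## Worked example

```r
library(envshift)

# 200 cells, three 800 s sessions; 11.5% of cells shift +4.0 spikes/s and
# 7.5% shift -5.7 spikes/s in the middle (object) session
g   <- generate_triplet(sim_config(n_cells = 200, seed = 1))
cls <- classify_triplet(g$triplet)          # 765 s window, 10 blocks
summarize_population(cls, "object")[c("pct_significant", "pct_increase",
                                      "pct_decrease",
                                      "mean_delta_increase",
                                      "mean_delta_decrease")]
#> $pct_significant   19
#> $pct_increase      11.5
#> $pct_decrease      7.5
#> $mean_delta_increase  4.03
#> $mean_delta_decrease  5.71
```

The numbers read: 19% of cells changed MFR systematically in the
manipulation session (11.5% up, 7.5% down), with mean shift magnitudes of
about 4.0 and 5.7 spikes/s — the classifier recovering exactly what the
generator injected.

The numbered drivers under `analysis/` run the full study on the reference
simulation and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # dataset + ground truth
Rscript analysis/02_classify_mfr.R  # MFR-change classification
Rscript analysis/03_speed_tuning.R  # speed-sensitivity census
Rscript analysis/04_ratemaps.R      # example ratemaps
Rscript analysis/05_popvec.R        # population-vector correlations
```

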