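---
title: "Methods: detecting systematic mean-firing-rate change in A-B-A' session designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting systematic mean-firing-rate change in A-B-A' session designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envshift)
```

## The problem and the design

Neurons in association cortices can signal a *change in the environment*
not by remapping where they fire but by shifting how much they fire. The
design this package analyzes is an A-B-A' triplet of foraging sessions: a
baseline arena, a manipulated middle session (object insertion, 45°
rotation, square-to-circle geometry change, wall expansion, or wall
removal), and a return to the baseline configuration. A cell that carries a
rate code for the manipulation should shift its mean firing rate (MFR) in
the middle session *and shift back* afterwards. Cells present in all three
sessions enter the classifier; all analyses use only the first 765 s of
each recording so every session contributes the same amount of data (765 s
is the shortest admissible session; shorter sessions are excluded rather
than padded). Time intervals are half-open `[t0, t1)` everywhere —
truncation, blocks, 400 ms bins, speed bins — which makes every bin count
deterministic (e.g. exactly 1912 complete 400 ms bins in 765 s, remainder
discarded).

## The MFR-change classifier

Each 765 s session is divided into ten equal blocks of 76.5 s and the MFR
of each block computed, giving three groups of ten block rates. The mean of
the ten block MFRs equals the session MFR exactly (equal block lengths), so
the block decomposition loses nothing at the session level while exposing
within-session variability to the test.

The criterion "the manipulation session differs from both flanking
sessions" is operationalized as: a Kruskal-Wallis omnibus over the three
groups, then Scheffé-type pairwise comparisons on the pooled ranks (the
convention of MATLAB's `multcompare` after `kruskalwallis`), requiring
**both** manipulation-vs-pre and manipulation-vs-post to be significant at
α = 0.05 with a consistent sign of Δ = MFR~manip~ − mean(MFR~pre~,
MFR~post~). Design choices worth making explicit:

* A literal "every block differs from every block" reading would mean 100
  pairwise block comparisons with no coherent error control; the
  omnibus-plus-post-hoc operationalization tests the same scientific claim
  with family-wise control.
* The Scheffé criterion on ranks (`P(chi²_{k−1} > t²)` for the standardized
  mean-rank difference `t`, with tie adjustment) controls the family-wise
  error for all contrasts simultaneously and is therefore conservative;
  false increase/decrease labels require *two* such tests to fire with a
  consistent sign, so the null false-label rate is far below α (measured
  ≈ 0 over 1000 simulated null cells in the test suite).
* Pre-vs-post significance does **not** veto a label; it is reported as a
  quality flag (`pre_post_differs`). The flanker reference for Δ is the
  symmetric mean of pre and post.
* The criterion is symmetric in the flankers, and because ranks are
  invariant under monotone transforms, relabeling time units cannot change
  any label.

At the calibrated effect sizes (+4.0 spikes/s on ~3 spikes/s baselines,
−5.7 spikes/s on ~8.7 spikes/s baselines) a shifted cell separates its 30
block ranks almost deterministically, so sensitivity is ≈ 1 and the
recovered population percentages land on the generator's 11.5% / 7.5%.

## Speed tuning

Instantaneous speed is the finite difference of the 30 Hz tracked position
(`v[i] = ||p[i] − p[i−1]|| · 30`), with a centered 5-frame boxcar smoother
by default (tracking jitter otherwise inflates speed; the smoother is a
parameter, including off). Tuning statistics use 25 bins of 2 cm/s spanning
5–55 cm/s; visualization uses 0–60 cm/s in 2.5 cm/s bins with the three
sessions concatenated — two deliberately different grids, because the very
slow and very fast tails are too thinly sampled for stable statistics but
still informative to look at.

Per-bin rate is spikes assigned to frames in the bin divided by time spent
there. A bin must hold at least 1 s of occupancy to be *defined*; extreme
speeds are visited for fractions of a second per session, and a rate
estimated from 0.1 s of data has essentially infinite variance.

Speed sensitivity is tested by comparing a uniform fit against a linear fit
of the defined bins, `F = (RSS₀ − RSS₁)/(RSS₁/(n−2))` on `(1, n−2)` df.
**Both fits are occupancy-weighted by default.** This is the one place the
package departs from the most naive reading of "fit the curve": the
sampling variance of an occupancy-normalized rate is proportional to
1/occupancy, so ordinary least squares hands its largest leverage to the
noisiest (sparse, extreme-speed) bins, and in simulation the unweighted
test rejects true-null cells at 10–15% instead of 5%. With occupancy
weights the measured null rejection rate is ~0.054 (2000 simulated null
session-curves), inside the nominal band. Unweighted fitting remains
available (`weights = "none"`).

A cell is *speed-sensitive* if any of its three sessions gives p < 0.05.
This any-of-three union necessarily inflates the population fraction above
the per-session rate (by up to 3α for truly flat cells) — that inflation is
a property of the rule, not a bug, and the recovery tests budget for it.

Shape categories (increasing / preferred / decreasing) are assigned from
the merged display curve by the tercile of the peak bin, confirmed by a
material-modulation margin: the mean rate of the peak tercile must exceed
the opposing tercile's (both, for "preferred") by 10%. The margin is what
keeps noisy flat cells out of the monotone categories — the argmax of a
flat curve always lands *somewhere* — and in simulation roughly two-thirds
of flat cells end up `unclassified`. The categories are an explicit,
testable convention for a distinction that is qualitative in the field.

## Ratemaps

Occupancy uses 3 cm bins; each 30 Hz sample deposits one frame interval
(1/30 s) in its bin, so occupancy sums exactly to the session duration.
Spikes are assigned to the spatial bin of the temporally nearest sample
(sub-frame interpolation buys nothing at 30 Hz for 3 cm bins). Raw rate is
spikes/dwell-time per bin; unvisited bins are masked and excluded from
everything downstream, with no minimum-dwell filter beyond "visited".

Smoothing uses an isotropic Gaussian. A "7 cm" kernel is ambiguous (σ?
FWHM? support?); the package takes σ = 7/3 cm ≈ 2.33 cm with the support
truncated at a 7 cm half-width, so ±1.5σ — essentially the kernel's whole
effective span — covers the nominal 7 cm; σ is an explicit argument, so
σ = 7 cm is one flag away. Normalization is *masked*: at each visited bin
both the numerator and the kernel weights are renormalized over the visited
support, so a constant field is preserved exactly and no mass bleeds in
from unvisited pixels. This conserves `Σ rate·occupancy = spike count`
before smoothing, and the occupancy-weighted mean of the raw map equals the
session MFR as an algebraic identity — both are asserted exactly in the
tests.

For display, a cell's three smoothed maps are divided by the 95th
percentile of the pooled visited-bin rates across the triplet, putting all
three sessions on one comparable color scale (values above 1 are expected
in ~5% of bins by construction).

## Population-vector correlations

For a fixed roster, the whole-session MFR vector of each session type is
Pearson-correlated (a rank option exists) with each 400 ms binned rate
vector of each session, pooling across triplets by concatenation into four
distributions: same-type, pre×manip, pre×post, manip×post. Bins in which no
roster cell fired have zero variance and undefined correlation; they are
excluded and counted, never imputed as zero (imputation would pile mass at
an arbitrary value and bias every comparison). The four distributions are
compared with the same Kruskal-Wallis + Scheffé machinery as the
classifier.

## The simulator

The generator exists so that every stage has ground truth. Its defaults
*are* the reference study conditions: 200 cells, three 800 s sessions
(truncated to 765 s for analysis) in a 125 cm square arena, 11.5% of cells
shifting +4.0 spikes/s and 7.5% shifting −5.7 spikes/s in the middle
session only, baselines drawn from a Gamma with mean 3 spikes/s (shape 4 —
right-skewed, strictly positive, matching typical cortical MFR
distributions). Decrease cells draw their baseline 5.7 spikes/s above the
Gamma so the shifted-down rate remains positive and comparable to the other
cells — a −5.7 shift is only realizable in cells that fire at least that
much. 70% of cells are speed-tuned (25% increasing, 25% decreasing, 20%
preferred with a random preferred speed in 15–45 cm/s), drawn independently
of the shift labels so the speed census and the MFR classifier can be
validated against orthogonal truths.

*Trajectories* use an Ornstein-Uhlenbeck velocity process (relaxation 2 s,
per-component sd 14 cm/s) with reflecting boundaries: smooth heading, a
Rayleigh-like speed distribution with mean ≈ 17.5 cm/s and negligible mass
above 60 cm/s — realistic pellet-chasing statistics — and ≥ 90% coverage of
the 3 cm grid in 765 s, the premise of any occupancy-normalized map. The
three sessions use independent trajectories with identical statistics; the
generator deliberately injects no cross-session behavioral differences, so
any detected rate effect is neural by construction (an option to break this
exists for robustness work).

*Spikes* are inhomogeneous Poisson by thinning: λ(t) = baseline ×
speed-gain(v(t)) × spatial-field(x, y), piecewise-constant per video frame
(33 ms, far below the 400 ms analysis resolution, so discretization cannot
bias any statistic). Gain functions are normalized to mean 1 over the
session so the baseline remains the expected MFR regardless of tuning. Each
cell/session pair gets its own RNG stream derived from (seed, cell id,
session), so adding cells never perturbs existing ones and every run is
exactly reproducible.

*Drift.* For population-vector experiments the generator can ramp each
cell's rate linearly by ±60% (random sign per cell) across the concatenated
triplet. The amplitude was fixed once, as the regime in which day-scale
drift dominates the shifted subpopulation's effect on cross-session
correlations — producing the qualitative gradient of interest: same-type
correlations highest, pre×post (the largest temporal separation) the lowest
cross-type median. Default is drift off.

What the simulator does **not** emulate: object-directed investigation
bouts, reward-seeking structure, place/grid/head-direction tuning beyond an
optional single Gaussian field, non-Poisson spiking (bursting,
refractoriness), and electrode drift. Passing tests therefore demonstrate
correctness of the *analysis* under a faithful null and a calibrated
alternative — not that real retrosplenial data meet these assumptions.

## Numerical conventions and degenerate inputs

* Truncation keeps `t < 765` strictly; a spike at exactly 765 s is dropped.
* Identical values in all Kruskal-Wallis groups: H = 0, p = 1 (the
  statistic is undefined under total ties; this is the only consistent
  limit).
* Perfectly linear tuning curves (RSS₁ = 0, slope ≠ 0): p = 0 with a
  `perfect_fit` flag; perfectly constant curves: F = 0, p = 1.
* All-silent cells classify as `none` with a `silent` flag rather than
  erroring, so population summaries over mixed-quality rosters stay total.
* Empty rosters warn at triplet assembly and error at pipeline entry.
* Unsorted spike files are sorted with a warning; spikes beyond the stated
  session duration are a hard validation error (they indicate a
  misalignment, not noise).

## Problem sizes

The test suite and the acceptance script run the reference 200-cell
triplet, a 1000-cell null population for classifier specificity, 2000 null
session-curves for F-test calibration, and 400-curve Monte Carlo batches
for the smaller properties; these sizes put Monte-Carlo error comfortably
inside each asserted band while keeping a full run in minutes on one core.

## Known limitations

* The Scheffé-type post hoc is conservative; cells with marginal shifts
  (≲ 1 spikes/s on low baselines) will be under-detected relative to a less
  protected procedure.
* The classifier assumes within-session stationarity; a strong monotone
  drift *within* the manipulation session can defeat the block test in
  either direction. Block MFRs are reported per cell so such cells can be
  inspected.
* Speed-tuning shape categories are a convention; near-tercile-boundary
  peaks are sensitive to the margin parameter.
* The population-vector analysis pools a pseudo-population; it does not
  model within-animal correlation structure.
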