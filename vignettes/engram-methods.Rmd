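---
title: "Methods: ensemble detection and reactivation analysis for dCA1 fear-memory imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble detection and reactivation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engram)
```

## Scope

`engram` re-implements, as a tested pipeline, the analysis chain used to
deconstruct a dorsal-CA1 fear-memory engram from miniscope calcium imaging
and pose-tracked behavior: freezing classification (the online closed-loop
criterion and a post-hoc windowed classifier), scheduling of
behavior-conditioned light-delivery ("tagging") epochs, calcium-event
extraction, assignment of cells to period-tuned ensembles by two methods,
bootstrap overlap verdicts, cross-session reactivation metrics, and
pairwise event-correlation tests against circular-shift nulls. A seeded
synthetic-session generator with planted ground truth stands in for raw
recordings, so every stage is verifiable end to end without data
downloads.

The package deliberately consumes *extracted* data products: fluorescence
trace matrices, pose tables, and cross-session registration maps. Trace
extraction from video, pose-network training, and probabilistic footprint
registration are upstream tools' jobs and are out of scope.

## Behavior: freezing classification

Body-part speeds are displacement per frame times the frame rate, in cm/s;
the first frame's speed is defined as 0 (no predecessor; conservative for
freezing). The **online** criterion mirrors the closed-loop tagging rig:
a part is immobile below 0.5 cm/s, and a frame is freezing when at least
`min_immobile_parts` of the ten tracked parts are immobile. Two variants
are used on purpose: 7-of-10 for freezing-tag sessions (tags contain as
much true freezing as possible) and 6-of-10 for no-freezing-tag sessions
(the complement excludes ambiguous frames). Lowering the part criterion
can only grow the freezing set, a monotonicity the tests assert.

The **post-hoc** classifier operates on recorded video tracking with five
parameters: centroid-speed threshold 0.3 cm/s, head-direction-change
threshold 12 degrees (nose-to-neck vector angle between consecutive
frames; both parts are in the tracked set), window width 32 frames, count
threshold 10 frames, minimum bout duration 0.5 s. The original
implementation's internals are not published beyond these parameters, so
the windowed rule here is this package's own definition, honoring all
five literally: a frame is a candidate when it qualifies (speed and angle
below threshold) *and* at least 10 frames qualify within its centered
32-frame window; candidate runs shorter than 0.5 s are discarded.
Requiring the frame itself to qualify makes the window act as glitch
rescue inside a bout rather than dilating bouts into flanking motion — an
isolated 0.4-s stationary interval is correctly rejected by the
minimum-duration rule, while a pure window-count reading would smear it
past the minimum. No temporal smoothing is applied before thresholding
(the closed-loop system's smoothing, if any, is not described).

Frame-to-seconds conventions: frame `f` (0-based) covers
`[f/rate, (f+1)/rate)`; bouts are maximal runs of frozen frames converted
to half-open second intervals, and rasterizing bouts back to frames
reproduces the per-frame labels exactly.

Freezing summaries are per-epoch percentages (frozen time over epoch
length, computed in continuous time from bouts) and
delta-freezing = mean % over light-ON epochs minus mean % over light-OFF
epochs, the standard readout for light-driven freezing.

## Tagging-epoch scheduling

Session timelines are fixed by protocol: fear conditioning (FC) is 7 min
with four 2-s foot shocks at minutes 2–5; recall is 8 min; immediate
shocks sit at seconds 2, 8, 14, 20 of a 40-s session; grouped shocks at
2:00, 2:06, 2:12, 2:18 of a 5-min session. Conditions map to light epochs
as: pre-shock, the two minutes before the first shock; shock, one 10-s
epoch per shock starting at shock onset (2-s shock + 8 s after, giving the
protocol's 40-s total); freezing, freezing bouts after the *offset* of the
third shock accumulated in order up to a 40-s budget with the last bout
truncated mid-bout; no-freezing, the complement of freezing from the
second shock's offset, same budget; recall variants accumulate over the
whole session without additional conditions. "After the n-th shock" is
read as after the shock's offset, since light during the shock itself
belongs to the shock condition. Budget shortfalls (not enough eligible
time) are flagged on the plan, not raised, because they are a legitimate
experimental outcome. Laser power and pulse patterns are metadata only.

## Event extraction

Traces are averaged in non-overlapping 1-s bins (trailing partial bin
dropped), z-scored per cell against the binned mean and population SD
(divisor n), and floored: bins below 2 SD are zeroed, survivors keep
their z value. The stated order — bin, then z-score, then threshold —
follows the procedure's sentence order and makes the 2-SD cut scale-free,
so the event raster is invariant under any positive rescaling of a trace.
Events are strict local maxima of the thresholded series (boundary bins
compare to their single neighbor); plateaus of exactly equal surviving
bins yield no event under strict inequality — a documented, configurable
tie rule that in practice never triggers on continuous-valued data. No
minimum prominence is imposed beyond the 2-SD floor. Overall activity is
the mean of each cell's binary row, in events/s. Zero-variance cells
yield all-zero rows and are flagged, never silently dropped.

## Ensemble detection

**Activity ranking.** For each condition, each cell's raw trace is
averaged over the would-be tagging epochs; cells strictly above the
across-cell mean plus one population SD of those in-epoch means are
members. With i.i.d. normal in-epoch means this captures the upper
~15.9% tail. The in-epoch mean is computed on raw samples (identical to
binned means for whole-second epochs, the usual case).

**Circular-shift permutation test.** Per cell, the statistic is the ratio
of mean 1-s-binned activity inside the condition epochs to the mean
outside, compared with the same statistic under 1000 random circular
shifts of the binned series (uniform offsets in `[1, n_bins − 1]`; the
null is computed for all offsets at once via FFT cross-correlation). A
cell is a member when its real ratio strictly exceeds the nearest-rank
95th percentile of its null. Shift replicates with exactly zero
out-of-epoch activity have an undefined ratio and are redrawn; a real
series with all activity in-epoch gets an infinite ratio (always a
member); all-zero cells are non-members, flagged. Because rotations of a
cell's series are exchangeable, the test's false-positive rate on
stationary untuned cells is ~5% by construction — the calibration the
acceptance suite measures. The test operates on the *pre-threshold*
binned series (the procedure names the calcium trace, not the event
raster).

Recall-session ensembles reuse the same machinery with epochs equal to
the freezing bouts (frz-recall) or their complement (no-frz-recall); an
entirely unfrozen (or entirely frozen) recall session is an error, since
the corresponding group is undefined.

**Topography.** Group-to-group distance is the mean over cells of X of
the distance to the nearest cell of Y in the field of view, keeping only
the smallest distance per cell; the measure is asymmetric by
construction, and self-distances are excluded when a cell belongs to
both sets.

## Overlap statistics

Overlap between two member sets is "the proportion of cells classified as
part of both"; the denominator is not pinned down by that phrase, so the
package defaults to Jaccard (`|A∩B| / |A∪B|`) and makes the alternatives
(`min` group size, session cell count) configurable. Verdicts are robust
to the choice because the bootstrap null uses the same metric: each of
1000 resamples draws two uniform random subsets of the observed sizes and
records their overlap. Groups are *overlapped* strictly above the
nearest-rank 95th percentile of the null, *non-overlapped* strictly below
the 5th, otherwise `ns`. 1000 resamples matches the permutation budget
used elsewhere in the pipeline; which sets are resampled is not specified
upstream, and both-sets-resampled is the chosen scheme.

One calibration caveat is inherent and worth stating: with ~90 cells and
~14-cell groups the overlap statistic is a small-count variable, and the
chance of an empty intersection (~7.6%) exceeds 5%. The null's 5th
percentile is therefore 0 and the strict "below the 5th percentile"
verdict can never fire at these sizes — the non-overlapped verdict is
conservative, with a realized rate of 0% rather than the nominal 5%. This
is a property of percentile verdicts on discrete statistics, not of the
implementation; the acceptance suite measures it and the corresponding
check documents the shortfall honestly. The overlapped side is close to
nominal (~4%). No multiple-testing correction is applied across pairs,
matching the source procedure.

## Cross-session reactivation

Registration maps are injective cell-index correspondences consumed, not
computed. Relative reactivation of a group is the fraction of its cells
tracked into recall divided by the overall tracked fraction; chance is 1,
and the worked example (100 cells, 70 tracked, 10-cell group with 5
tracked → 50%/70% ≈ 0.71) is pinned in the tests. Under uniform random
tracking the metric is unbiased (mean → 1 across simulated animals,
conditioning on nonzero tracking). Recall activity reports, per group:
tracked count, mean event rate over the whole recall session (imaging
sessions carry no light epochs, so no exclusion arises), rates inside and
outside freezing bouts, and their ratio with division-by-zero flagged
rather than dropped. Group composition reports the percentage of tracked
members that are frz-recall members. The "others" group — cells in both
sessions belonging to no condition ensemble — can be formed by callers
from the membership lists; reports are per animal, with group-level
statistics left to the caller.

## Correlations and their nulls

Pairwise Pearson correlations are computed on the binary 1-s event
arrays for every unordered pair of non-degenerate cells. Event arrays
(rather than binned z values, which remain available) are the default so
that the observed table and its circular-shift null operate on the same
object. The null shifts every cell's event array by an independent
uniform offset 1000 times, conserving per-cell event counts exactly while
destroying pairwise timing. A group slice (e.g. freezing–freezing pairs)
is *significant* when its observed mean r strictly exceeds the
nearest-rank 95th percentile of the per-replicate null means — a
one-sided test at 5%, this package's definition since the upstream
comparison is not named; comparing to a same-slice null controls for
sample-size effects. Cumulative distributions of observed and pooled null
r are returned for plotting. A null with fewer than 1/α replicates cannot
resolve the percentile and is flagged underpowered instead of guessing.

## The synthetic-session generator

The generator emulates the study's conditions, not its biology. Freezing
is a two-state alternating renewal process with exponential dwells,
started at stationarity (mean bout 4 s, mean inter-bout 16 s by default,
i.e. 20% freezing occupancy), generated in continuous time and rasterized
to frames with sub-frame bouts dropped. The pose track is a centroid
random walk in a 24-cm arena at 15 fps carrying the ten tracked parts at
fixed body-frame offsets: frozen frames hold position and heading with
0.002-cm tracking jitter (all part speeds well below 0.5 cm/s), moving
frames translate at 2–8 cm/s with a wandering heading (essentially all
parts above threshold). Only the speed statistics are meaningful — there
is no place coding, thigmotaxis, or rearing.

Traces are sampled at 20 Hz: each sample is an event with probability
rate/20, where the rate is a 0.02 events/s baseline, multiplied by the
in-period gain inside a planted cell's condition epochs; events are
convolved with a unit-amplitude single-exponential kernel (τ = 0.5 s,
fast-indicator-like; the exact value is immaterial to the statistics) and
Gaussian noise of SD 0.1 is added. Ground-truth event times are returned
alongside. Planted cells are tuned to the *would-be tagging epochs*
derived from the session's own simulated behavior, which is exactly the
quantity the detection methods estimate.

Reference conditions: 90 cells per session (the typical per-session
yield, range ~47–172), four planted 14-cell ensembles, in-period gain 10,
70% cross-session tracking. The ensemble size matches the ~15.9% fraction
the mean-plus-one-SD ranking rule captures; the gain follows a power
calculation: a 40-s condition window at baseline 0.02 events/s holds
0.8 expected background events, and ~8 expected in-window events
(gain 10) are needed for the rank threshold to separate tuned from
background cells reliably, whereas gain 5 (~4 events) leaves a
Poisson-noise recall ceiling near 0.75. In-period gains for genuinely
tagged cells are not reported upstream, so these are free parameters of
the benchmark, chosen once — passing recovery tests demonstrates the
pipeline's correctness at this effect size, not performance on real
recordings, where effect sizes, rate heterogeneity, and correlated noise
are unknown. Registration drop-out is independent Bernoulli per cell,
optionally group-specific for power experiments; real registration errors
(mismatches, spatially structured drop-out) are not modeled.

All randomness flows through one seeded generator per call; identical
(spec, truth, seed) reproduce outputs bit for bit.

## Numerical choices

Percentiles are nearest-rank throughout (`sorted[ceil(p/100 · n)]`), with
strict inequalities at every cut. Population SD (divisor n) is used for
the ranking threshold and z-scores. Sample and frame midpoints decide
epoch membership (`sample s` belongs to an epoch iff its midpoint lies in
the half-open interval), making whole-second epochs exact. The
statistical detector treats `|out-of-epoch sum| ≤ 1e-9 · (Σ|x| + 1)` as
zero for the undefined-ratio rule. Stage seeds derive deterministically
from the global seed and stay within 32-bit integer range. Problem sizes
in the test suite (sessions of 60–90 cells, 1000-cell calibrations,
50-seed recovery averages, 1000–10,000-replicate bootstraps) were chosen
so the full suite completes in a few minutes on one CPU while keeping
Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

Cell ids are 1-based integers everywhere, including on disk. The rank
and statistical detectors share the session's binned representation but
are otherwise independent; their agreement on synthetic data (reported as
Jaccard over membership assignments) depends on effect size and should
not be read as a property of real recordings. The post-hoc classifier is
a re-interpretation, not a port, of the original windowed classifier.
Group-level inference across animals (ANOVAs on freezing percentages,
animal-level error bars) is intentionally left to the caller, as are
graph analyses of correlation matrices and any multiple-testing
correction across overlap pairs.
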