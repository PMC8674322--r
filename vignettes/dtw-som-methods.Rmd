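---
title: "Warping-aligned self-organizing maps for diurnal exposure patterns: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warping-aligned self-organizing maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of what it computes and why: the
distance and the map model, the preprocessing contract, the synthetic data
the tests rely on, the numerical choices made where the design was genuinely
open, and the limits of what the shipped tests demonstrate.

```{r setup, message = FALSE}
library(dtwsom)
```

## 1. Dynamic time warping

Two day-series `a` (length `T_a`) and `b` (length `T_b`) are compared by the
minimal cumulative cost of a *warping path* — a sequence of index pairs
`(i, j)` starting at `(1, 1)`, ending at `(T_a, T_b)`, advancing by `(1,0)`,
`(0,1)` or `(1,1)` (monotone, unbroken). The local cost is `|a_i - b_j|` and
the path cost is the plain sum along the path: no squared costs, no
path-length normalization, unit step weights. The dynamic program fills
`D(i,j) = |a_i - b_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1))` and backtracks
one optimal path. Optimal paths are not unique, so backtracking ties are
broken deterministically: diagonal first, then the step advancing `a`.

A Sakoe-Chiba band restricts the search to `|i - j| <= band`. The band is a
half-width in samples on each side of the diagonal; with unequal lengths it
must be at least `|T_a - T_b|` or no admissible path exists (rejected with a
message). The default `band = 60` corresponds to one hour at minute
resolution: alignments are allowed to stretch time locally by up to an hour,
which comfortably covers the within-day timing variability the method is
meant to absorb. `bandApproximationError()` measures the cost of the
restriction on synthetic diurnal pairs; at warp magnitudes up to 30 min the
banded distance is typically *identical* to exact (median relative
difference 0%, maximum well under 1%), which is why the banded distance is
used throughout training.

The DP core is C++ (`src/dtw.cpp`): a 1440x1440 cost matrix is ~2 million
cells per call and training performs thousands of calls. A pure-R
exhaustive-enumeration oracle (`dtwOracle()`, series up to length 8, no
dynamic programming, no shared code) provides the independent reference the
test suite checks the DP against on a thousand random pairs.

Approximate-DTW schemes that coarsen and refine the series are deliberately
not implemented; on series of this length the exact banded DP is already
fast, and multi-resolution approximations have been reported slower than
well-implemented exact DTW in practice.

## 2. The three map variants

A self-organizing map places `R x C` neurons on a lattice, each carrying a
weight vector of the series length. Online training repeats: draw one input
(shuffled cycling), find the best-matching unit (BMU), update every neuron
`r` by its kernel weight `h_rs = exp(-d(r, s)^2 / (2 sigma^2))` toward the
input. The package ships three variants differing in where DTW enters:

| variant     | BMU metric | weight update                  |
|-------------|-----------|---------------------------------|
| `euclidean` | Euclidean | timestamp-aligned (`updateEuclidean`) |
| `dtw_match` | DTW       | timestamp-aligned               |
| `dtw_full`  | DTW       | warping-aligned (`updateDtw`)   |

The warping-aligned update is the substantive piece. For each pair
`(t, t-bar)` on the DTW path between the neuron `W` and the input `x`, with
step size `eh = epsilon * h`:

* value: `v = W_t + eh * (x_{t-bar} - W_t)`
* pseudo-timestamp: `t~ = t + eh * (t-bar - t)`

so the value *and its timing* move toward the input by the same fraction.
This choice makes the rule exact at both ends — `eh = 0` is the identity and
`eh = 1` reproduces `x` bit-for-bit — and reduces to the classic rule
whenever the optimal path is the diagonal (both facts are tested). DTW
alignments are many-to-one, so several pairs can land on one `t~`: their
values are averaged. The resulting `(t~, v)` points form a piecewise-linear
curve that is resampled onto the integer timestamps; the boundary path pairs
pin `t~` to the ends, so resampling is interpolation, never extrapolation,
and trained weights can never leave the value range spanned by the data
(also tested). Each updated neighbor computes its *own* path to the input
rather than reusing the BMU's: neighbors far from the BMU in weight space
would otherwise receive updates aligned for a different shape.

### Kernel space

The kernel distance `d(r, s)` defaults to the *lattice* distance between
neuron positions — the standard SOM choice, and the one that gives the
trained map its 2-D topology (season gradients across the grid,
Moore-neighbor coherence). A `dtw_weightspace` option instead uses the DTW
distance between the two neurons' weight vectors; it is provided because the
alternative reading is defensible, but it abandons the lattice topology, so
it is not the default and the package does not guess which the original
analysis used.

### Schedules and defaults

None of these are dictated by the method; they are conventional SOM practice
and all configurable through `trainConfig()`:

* `iterations = 3000` online updates — the scale at which weight convergence
  was observed in the motivating analysis; the quantization-error trace
  (`qeTrace()`) is emitted so users can verify a plateau rather than trust
  the count.
* `epsilon = c(0.5, 0.01)`, exponential decay.
* `sigma = c(max(R, C)/2, 0.2)`, exponential decay. The end value implements
  the classic ordering-then-tuning regime: at `sigma = 0.2` the kernel
  weight of even the nearest lattice neighbor is `exp(-12.5) ~ 4e-6`, below
  the update cutoff, so the final phase is winner-only fine tuning. A larger
  end width (e.g. 0.5, nearest-neighbor weight 0.135) leaves permanent
  cross-talk between adjacent neurons: on two constant prototypes 0.6 apart
  the equilibrium contamination is ~0.6 * 0.135/1.135 ~ 0.07, which is why
  prototypes would then never be recovered to better than ~0.05.
* `kernel_cutoff = 1e-3` skips negligible updates — an efficiency cutoff
  whose per-step effect is below 1e-3 by construction.
* `init = "sample"` draws initial weights from the data (with replacement
  plus a warning if the grid outnumbers the inputs); `"random"` draws
  uniformly over the data range.
* One integer seed makes the entire run — initialization, input order —
  reproducible; reruns are byte-identical.

## 3. Preprocessing contract

`preprocessExposures()` applies the cleaning chain in a fixed order:

1. median filter (kernel 3) per sensor stream — the smallest window that
   removes isolated one-minute outliers; edges use nearest-value padding
   (length-preserving, fabricates no values), windows skip missing entries
   and missing points stay missing;
2. duplicate sensors averaged per minute; a minute is missing only when all
   sensors miss it;
3. gaps of **60 minutes or more** are truncated (left missing, reported);
   shorter interior gaps are linearly interpolated between their flanking
   values. The boundary case — exactly one hour — is assigned to
   truncation, and gaps touching a stream end are never extrapolated;
4. pollutant values min-max scaled to [0, 1] using the *group-wide* range
   per variable and location across all sites and days, so between-day
   amplitude differences survive scaling and the transform is invertible
   from the stored `(min, max)`. Temperature stays in native degrees by
   default (`scale_temperature = TRUE` opts in) — weight and variance
   summaries for temperature are therefore in native units;
5. non-overlapping 1440-minute windows anchored at 20:00 (questionnaire
   time); windows with any missing value or fewer than 1440 points are
   dropped, so every emitted day is complete by construction;
6. daily outcomes joined on site + window-start date; unmatched days keep
   `NA` and are excluded from outcome overlays but retained for clustering.

Interpolation runs on the continuous stream *before* windowing, so short
gaps spanning a window boundary are still filled. Seasons are meteorological
(Dec-Feb winter, etc.) by the window-start month. The result is an
`ExposureDays` object — a `SummarizedExperiment` whose assay is the
`1440 x M` day matrix and whose `colData` carries site, date, variable,
location, season and outcome — so the usual Bioconductor subsetting applies.

## 4. What the synthetic generator emulates — and what it does not

`simulateExposure()` emulates the *structure* of a residential sensor panel:
several sites; smooth noon-peaked temperature days whose baseline and
amplitude follow a seasonal model; PM days built from a low baseline plus
Gaussian-shaped spikes (SD 20 min) at jittered morning/evening anchors with
Poisson day counts; duplicated indoor sensors; additive Gaussian noise; a
random monotone time warp per day; missing gaps in a short/long mixture; and
a daily binary outcome from a logistic model on the standardized indoor-PM
spike count and daily SD (coefficients in the config, so outcome signal
strength is tunable).

The warp model is a strictly increasing, endpoint-fixed piecewise-linear
time map with four interior knots displaced uniformly within the warp
magnitude — simple, controllable, and bounded: no timestamp moves by more
than the magnitude. This is exactly the nuisance DTW is designed to absorb,
and the generator records the realized map in the ground truth.

Not emulated: indoor-outdoor infiltration physics, sensor drift or
humidity-dependent calibration, particle-count-to-mass conversion, daylight
saving arithmetic, and the true timing/size distribution of household PM
sources (nothing quantitative is published for the motivating panel; spike
parameters are honest free knobs, not calibrated values). Consequently,
passing tests demonstrate the *algorithmic* claims — alignment-invariance,
shape preservation, correct bookkeeping — on data whose ground truth is
known, not that the package reproduces any particular study's numbers.

Two reduced benchmark sets keep tests tractable at length 144 instead of
1440: `simulatePrototypeDays()` (seasonal temperature prototypes, warped and
noised) and `simulateImpulseDays()` (a single sharp bump, peak 1, warped by
up to 30 samples — the regime where timestamp-aligned averaging visibly
flattens features). Series length scales the DP quadratically; length 144
keeps the full 10-seed training comparisons in minutes while preserving the
width-vs-warp geometry that drives the phenomena.

## 5. Evaluation metrics

* **Quantization error** `sqrt(mean ||x - W_BMU(x)||^2)`, full-series
  Euclidean norm, identical for every variant so they are comparable; the
  "centroid" is the assigned BMU's weight vector. A `per_timestamp` mode
  divides by series length first. The phrase "RMS error of moving inputs to
  their centroid" admits other readings (notably a DTW-aligned residual);
  this package fixes the timestamp-aligned Euclidean one and documents the
  consequence below.
* **Grid-size tuning** retrains across lattice sizes and returns the
  (neurons, QE) curve; a max-curvature elbow is attached as a suggestion
  only, since inflection reading is an analyst's judgement.
* **Moore-neighbor distance**: mean Euclidean distance of each neuron's
  weights to its existing 8-neighborhood, averaged over neurons — lower
  means smoother topology.
* **Cluster entropy** against a label such as season, in bits, two forms:
  the count-weighted mean of within-neuron entropies (ceiling
  `log2(#labels)`; 0 = every neuron pure) and the joint (neuron, label)
  entropy (ceiling `log2(#neurons * #labels)`). Both are reported because
  published "SOM entropy" values for 4-season labels exceed the 2-bit
  ceiling of the weighted form, so the intended formula there cannot be the
  weighted one; the package asserts nothing against those values.
* **Outcome fractions** per neuron: positive / known-outcome assigned days,
  with an explicit `NA` (not 0) when a neuron received no outcome-labeled
  day.

## 6. What the warping-aligned update does and does not buy

The shipped comparisons (10 seeds each, fixed conditions) show:

* **Shape preservation.** On warped copies of a sharp impulse, a
  single-neuron `dtw_full` map retains >= 0.8 of the unit peak and its
  weight variance tracks the input variance; the `euclidean` map flattens
  the peak to ~0.35-0.48 and halves the variance. This is the core claim of
  alignment-aware training, and it is robust.
* **Quantization error, measured timestamp-aligned, is a different story.**
  Euclidean training is (near-)gradient descent on exactly that statistic,
  so with equal neuron capacity it is structurally favored: on warped
  discrete prototypes the DTW map additionally concentrates all warped
  copies of a prototype onto one neuron (they are DTW-equidistant), leaving
  surplus neurons idle while the Euclidean map spends them on time-shift
  bins. Across every synthetic regime we examined (discrete prototypes,
  continuous per-day amplitude variability, spiky PM-like days, wider
  terminal kernels) the Euclidean variant's timestamp-aligned QE was equal
  or lower. The package still reports the three-variant QE table, but a
  user should read timestamp-aligned QE as measuring *compression under the
  Euclidean geometry*, which is not the geometry the DTW map optimizes;
  shape fidelity is better judged by the variance/peak diagnostics and the
  label-purity entropies.

## 7. Degenerate inputs and numerical conventions

* Empty series, non-finite values, and bands narrower than the length
  difference are rejected with messages naming the offence.
* BMU ties break to the lowest row-major neuron index; backtracking ties
  prefer the diagonal. Both make reruns reproducible.
* A constant scaling group (max = min) is an error naming the group, not a
  silent division by zero.
* `updateDtw` with a single alignment point (length-1 series) returns the
  constant; `epsilon * h` outside [0, 1] is rejected rather than clamped.
* All randomness flows through one seeded generator per entry point
  (`withr::with_seed`), never global state; identical configs give
  byte-identical artifacts, which the pipeline manifest's config hash makes
  checkable.

## 8. Known limitations

Univariate series only (one map per variable+location); online training
only (no batch/barycenter updates); the band applies uniformly (no
Itakura-style tapering); the outcome overlay is descriptive, with no
health-effect modelling on top. The timestamp-aligned QE caveat of section 6
is a property of the metric, not fixable by tuning, and is documented rather
than hidden.
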