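---
title: "Extracting and clustering miniature EPSCs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and clustering miniature EPSCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepsctools)
```

# The scientific problem

Miniature excitatory postsynaptic currents (mEPSCs) are the quantal building
blocks of synaptic transmission: brief inward currents recorded under
whole-cell voltage clamp while action potentials and inhibition are blocked.
Each release site produces events with a characteristic amplitude and
kinetics, so when a neuron is innervated by more than one *type* of
excitatory input, the joint distribution of event amplitude and decay time
can become multi-modal. `mepsctools` implements the full chain from raw
current trace to a per-cell answer to the question *"how many types of
excitatory input does this neuron receive?"*:

1. trace conditioning (high-pass, low-pass, mains-notch cascade);
2. threshold detection with a robust, percentile-trimmed threshold;
3. per-event fitting of a linear-rise/exponential-decay model;
4. plausibility bounds and an iterated PCA outlier screen;
5. a per-cell stationarity gate (regression-F tests, Bonferroni-corrected);
6. density-peak clustering of `{log amplitude, log decay}` with an automatic
   cluster-count rule.

A seeded synthetic-recording generator with known ground truth closes the
loop for validation.

# The event model

An event is modelled as a linear ramp followed by a single exponential:

$$
\mathrm{EPSC}(t) =
\begin{cases}
0 & t \le t_0 - \mathrm{Rise} \\
\mathrm{Amplitude}\,\dfrac{t - t_0 + \mathrm{Rise}}{\mathrm{Rise}} &
  t_0 - \mathrm{Rise} < t \le t_0 \\
\mathrm{Amplitude}\,e^{-(t - t_0)/\mathrm{Decay}} & t > t_0
\end{cases}
$$

with four parameters: `Amplitude` (pA, positive magnitude of the inward
peak), `Rise` (ms, full ramp duration), `t0` (ms, time of the peak) and
`Decay` (ms, the e-fold decay constant). Recorded events are the negation of
this template. A double-exponential alternative is deliberately out of
scope: with realistic noise its least-squares surface has multiple local
minima and yields unstable rise/decay estimates, whereas the piecewise model
is robust. The 10–90% rise time is derived analytically as `0.8 * Rise` —
exact for a linear ramp — rather than re-measured from noisy samples; this
makes it a deterministic function of the fit.

Fits use Levenberg–Marquardt least squares (`minpack.lm`) with numerical
gradients (the model is non-smooth at `t0` and `t0 - Rise`), all parameters
bounded positive and `t0` confined to the snippet. The baseline is fixed at
zero: preprocessing has already removed DC and drift, and the printed model
has exactly four parameters. Goodness of fit is
`R^2 = 1 - SS_res/SS_tot` over the fit window, stored unclipped (bad fits
can be negative). On noiseless model data the solver recovers all four
parameters to ~1e-16 relative error; this is asserted in the test suite.

## Fit window

The width of the window is a design choice: 5 ms before to 25 ms after the
detected peak, wide enough for the plausibility bounds (10–90% rise up to
10 ms, decay up to 15 ms). The window is truncated at the *next* retained
candidate's onset, and also at the *previous* retained candidate's offset.
The second truncation is not strictly part of the published recipe but is
required in practice: a candidate detected on the decay tail of a large
predecessor would otherwise see the predecessor's peak inside its own
window and re-fit that peak, duplicating events.

# Preprocessing

Three Butterworth stages in fixed order: high-pass at 5 Hz (de-trending),
low-pass at 4 kHz (de-noising), then a cascade of band-stop filters with
stopbands $n \cdot 50 \pm 1$ Hz for $n = 1..80$ (mains fundamental and
harmonics up to 4 kHz). Choices the published recipe leaves open:

* **Order**: 2 per stage. An 80-notch cascade must remain numerically
  stable; low order keeps each stage well conditioned.
* **Realisation**: each band-stop (an order-4 transfer function) is
  factored into two biquads (second-order sections) before filtering.
  Direct order-4 recursions with poles crowding the unit circle lose
  precision; with biquads the whole cascade is linear to better than 1e-8
  relative error, which the tests assert.
* **Phase**: zero-phase (forward–backward) application by default, so event
  timing — which the fit's `t0` and the stationarity regressions depend
  on — is not skewed by filter group delay.
* **Edges**: odd-reflection padding of roughly one settling length per
  stage (6/f_c for the high-pass, 1/halfwidth for the notches), so filter
  transients decay in the padding rather than in the data.

# Detection

The threshold is `trimmed mean - 4 * trimmed SD`, computed on samples whose
values lie between the 1st and 99th percentiles of the trace (linear
interpolation convention), limiting the influence of artifacts on the
moment estimates. One candidate is produced per maximal run of samples
below threshold, anchored at the run's minimum (the peak). Candidates whose
peak follows the last *retained* peak by less than 3 ms are removed: their
parameters would be biased by the preceding decay, and comparing against
the last retained event (rather than the last raw candidate) preserves the
first event of a burst — the one with an uncontaminated rise. Candidates
touching the first or last refractory window of the record are dropped as
unfittable. These conventions (peak-time anchoring, retained-event
comparison) are choices documented here, not claims about the original
authors' code.

# Quality control

Plausibility bounds, all strict inequalities as printed:
`R^2 > 0.3`, `0.1 < Decay < 15` ms, `0.05 < 10–90% rise < 10` ms,
`Amplitude < 200` pA. Each rejected event records the first violated rule.

The outlier screen applies PCA to the matrix of event time signals (one
event per row, aligned at the fitted `t0`, window equal to the fit window,
mean-centred per time point, no variance scaling). Events scoring strictly
beyond mean ± 6 SD on either of the first two components are removed and
the analysis is iterated until a fixed point (cap: 50 iterations; one
usually suffices). Scores are used raw — each component's own SD defines
its band — the literal reading of the rule. On clean simulated data the
screen removes ~0.1% of events; injected square-pulse artifacts are removed
exactly (asserted in the tests).

# Stationarity gate

For each cell, amplitude, 10–90% rise and decay are regressed against event
time; the F-test on (1, n−2) degrees of freedom judges the slope. A cell is
stationary iff all three p-values exceed `alpha / (n_params * n_cells)`.
Degenerate zero-variance parameters give `F = 0, p = 1` (constant is the
definition of stationary).

One numerical point deserves emphasis: for the widely used configuration of
3 parameters and 45 cells at family-wise 5%, the correction arithmetic
gives `0.05/135 = 3.70e-4` (0.037%), while the figures commonly quoted for
it — "0.37%" and 0.0037 — both equal 3.7e-3 and are mutually inconsistent
with that arithmetic. The package always computes the formula and prints a
provenance note in the run log surfacing the conflict; it never hard-codes
either quoted number. Manual exclusion of non-stationary recording
stretches is supported only as a config-driven interval list — the original
step was visual, and automating change-point detection is a non-goal.

# Density-peak clustering

Events are clustered in the `{log amplitude, log decay}` plane (natural
logs; the base is immaterial because the cutoff is a distance percentile,
so any common rescaling leaves the structure unchanged; per-axis
standardisation *would* change it and is deliberately not applied). For
each point:

* `rho` — the number of other points strictly closer than the cutoff `dc`
  (a hard count, not a kernel);
* `delta` — the distance to the nearest point of higher density, with
  density ties broken by point index so the "higher" relation is a total
  order (integer densities make ties common); the unique global maximum
  takes the largest pairwise distance in the data as its `delta`;
* `gamma = rho * delta^2` — the center score.

`dc` is a percentile of the n(n−1)/2 pairwise distances. Because a missed
cluster is considered worse than a spurious dc choice, the pipeline sweeps
four percentiles {0.5, 1, 2, 4}% and keeps the result with the most
clusters (ties go to the percentile closest to the typical 2%).

## The automatic center-count rule

The sorted-`gamma` plot "helps identify" the cluster count in the original
procedure — a human judgement. To make the pipeline reproducible the count
is automated: candidate centers are the top-`gamma` points, and the count
`k` is placed at the largest multiplicative gap `gamma_(k)/gamma_(k+1)`
among the top ten ranks. Two guards proved necessary in validation:

1. only points with `gamma > 0` (i.e. `rho >= 1` and `delta > 0`) are
   candidate ranks — a zero-density point cannot anchor a cluster, and
   gaps into the zero tail are meaningless;
2. a `k > 1` break is accepted only when its gap ratio dominates every
   other gap ratio by at least a factor of two. Without this, unimodal
   cells at the smallest swept percentile frequently show two near-tied
   gaps, and the max-over-dc sweep promotes the spurious split: the bare
   largest-gap rule recovered a single cluster in only 93/100 simulated
   unimodal cells, versus 99/100 with the dominance guard (two-population
   recovery stays at 100/100 with perfect label accuracy; these rates are
   recomputed by `scripts/acceptance.R`).

Any cluster holding less than 5% of the points triggers re-selection with
one fewer center — a cluster cannot build on a few percent of the data.
Fewer than 10 points always yield a single cluster with a warning. After
center selection, points are processed in decreasing density and each
inherits the label of its nearest denser neighbour. The implementation is
checked against an independent brute-force O(n^2) oracle for exact equality
of `rho`, `delta`, `gamma` and labels on 100 random instances.

# The synthetic-data generator

`render_recording()` emulates the statistical structure the analysis
assumes: per population, homogeneous-Poisson event times and log-normal
amplitude/rise/decay; events rendered with the same model used for fitting
(linear superposition — quantal events are small relative to the clamp
range, so no saturation); white Gaussian noise; 50 Hz interference with
geometrically decaying harmonics at uniformly drawn phases (interference
phase is uncharacterised in real rigs); and a slow baseline drift built
from a spline-smoothed random walk — any sub-5 Hz process suffices, since
preprocessing removes it. Defaults are 180 s at 20 kHz. Noise levels and
rates are not quantified in the published recordings, so the defaults are
chosen once at values a patch-clamper would call typical — noise SD 3 pA,
line amplitude 2 pA with 4 harmonics, drift 5 pA at 5 s timescale, rate
2 events/s, median amplitude 60 pA with log-SD 0.3, rise 0.5 ms, decay
2 ms — and everything is configurable.

What the generator does **not** emulate: series-resistance and space-clamp
distortion (which attenuate and slow dendritic events), amplitude/kinetics
correlations induced by cable filtering, non-Poisson release statistics,
and recording-wide artifacts other than mains and drift. Passing tests
therefore show that the pipeline recovers the structure it assumes, not
that real recordings satisfy those assumptions.

# Problem sizes and numerical conventions

The validation suite runs at sizes chosen to exercise every code path on a
desktop: cluster-recovery checks use 100 seeded cells of 300–500 events
per scenario; oracle-equality checks use 100 instances up to n = 200;
stationarity calibration uses 10,000 sequences of n = 200 and a 200-run
power check of a 30% run-down over 180 s (n = 300 events); end-to-end
recall uses a 30 s recording at 20 kHz. Percentiles use R's default
(type 7) linear interpolation throughout. Ties in density are broken by
index; ties in the dc sweep by proximity to 2%, then by the smaller
percentile. Degenerate inputs (constant traces, zero-variance parameters,
identical points) take documented conventions rather than errors wherever a
convention is scientifically meaningful.

# A worked example

```{r example, eval = FALSE}
spec <- recording_spec(duration = 60, seed = 42,
                       populations = list(
                         population_spec(median_amplitude = 30, median_decay = 1,
                                         rate = 1.5),
                         population_spec(median_amplitude = 120, median_decay = 4,
                                         rate = 1.5)))
rec <- render_recording(spec)
res <- analyze_trace(rec$trace)
res$counts        # detected -> refractory -> fit -> plausible -> PCA
res$stationarity  # three slopes, F, p, threshold
res$clustering    # n_clusters, dc, centers, labels
res$summary       # per-cluster medians
```

# Known limitations

* The cluster-count rule is a reproducible stand-in for a human reading of
  the decision graph; borderline cells (overlapping populations, < 4-fold
  separation) can fall either way, which is why the per-dc diagnostics and
  a decision-graph plot are exposed for inspection.
* Only delimited-text traces are read; binary acquisition formats must be
  exported to text first.
* Manual curation steps of the original workflow (visual artifact vetting,
  visual non-stationarity marking) are supported via plots and config
  exclusion lists, not automated.
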