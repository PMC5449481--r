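# mepsctools

Detection, model fitting and density-peak clustering of miniature
excitatory postsynaptic currents (mEPSCs) from whole-cell voltage-clamp
recordings — for electrophysiologists who want a reproducible, auditable
answer to the question *how many types of excitatory synaptic input does
this neuron receive?*

Miniature EPSCs are quantal synaptic events recorded as brief inward
current deflections while spiking and inhibition are pharmacologically
blocked. Distinct presynaptic input types produce distinct amplitude and
kinetics populations, so the joint distribution of event parameters carries
the answer. The package implements the full chain:

1. **Preprocessing** — Butterworth high-pass (5 Hz), low-pass (4 kHz) and a
   cascade of band-stop filters at n·50 ± 1 Hz, n = 1..80, removing mains
   interference and harmonics (zero-phase, second-order sections).
2. **Detection** — threshold at `trimmed mean − 4·SD` computed on samples
   between the 1st and 99th percentiles; one candidate per sub-threshold
   excursion; candidates within 3 ms of the last retained peak removed.
3. **Fitting** — each event fitted by Levenberg–Marquardt least squares
   with the four-parameter piecewise model

   ```
   EPSC(t) = Amplitude · (t − t0 + Rise)/Rise    for t0 − Rise < t ≤ t0
             Amplitude · exp(−(t − t0)/Decay)    for t > t0
   ```

   yielding Amplitude (pA), Rise (ms), t0, Decay (ms), the derived 10–90%
   rise time (= 0.8·Rise) and R².
4. **Quality control** — plausibility bounds {R² > 0.3; 0.1 < Decay < 15 ms;
   0.05 < 10–90% rise < 10 ms; Amplitude < 200 pA} plus an iterated PCA
   screen removing events beyond mean ± 6 SD on either of the first two
   components of the event-waveform matrix.
5. **Stationarity gate** — per-cell regression of each parameter against
   time, F-tested at a Bonferroni threshold `α/(n_params·n_cells)`.
6. **Clustering** — density-peak clustering of {log amplitude, log decay}:
   local density ρ (neighbour count within a cutoff dc), separation δ
   (distance to the nearest denser point), score γ = ρ·δ²; dc taken as a
   percentile of all pairwise distances and swept over {0.5, 1, 2, 4}%,
   keeping the result with the most clusters.

A seeded synthetic-recording generator (`render_recording()`) produces
traces with known ground truth — Poisson event times, log-normal parameter
populations, Gaussian noise, 50 Hz interference with harmonics, baseline
drift — and backs every validation claim.

## Worked example

Simulate a cell that receives two input types (4-fold separated in both
amplitude and decay), then run the whole pipeline:

```r
library(mepsctools)

spec <- recording_spec(duration = 60, seed = 42,
                       populations = list(
                         population_spec(median_amplitude = 30,  median_decay = 1, rate = 1.5),
                         population_spec(median_amplitude = 120, median_decay = 4, rate = 1.5)))
rec <- render_recording(spec)
res <- analyze_trace(rec$trace)

res$counts
#>         detected after_refractory    fit_converged        plausible
#>              432              269              268              191
#>        after_pca  after_exclusion
#>              191              191

res$stationarity
#> Stationarity report
#>   parameter         slope          F         p
#>   amplitude -0.0667186632 0.14060964 0.7080961
#>  rise_10_90  0.0033610393 0.90535188 0.3425659
#>       decay  0.0006509695 0.01236688 0.9115706
#> threshold 0.0167 -> stationary

res$clustering
#> density_result: 2 cluster(s) at dc percentile 2 (dc = 0.1303)
#>  cluster   n median_amplitude_pA median_rise_10_90_ms median_decay_ms
#>        1 108            25.74207            0.4075156        0.956378
#>        2  83           104.77244            0.3903166        3.634952
```

Reading the output: 432 threshold crossings shrink to 191 retained events
through the refractory rule, the fit-convergence check, the plausibility
bounds (which discard the noise-only crossings) and the PCA screen; all
three parameters are stationary over the minute of recording (every
p ≫ threshold), so the cell is clustered; the sweep finds two clusters
whose per-cluster medians recover the two implanted populations.

`run_pipeline("traces/", output_dir = "results/")` does the same for a
directory of delimited-text traces and writes per-cell event tables, JSON
summaries (including the full decision log) and a cross-cell table. A thin
command-line wrapper with `simulate` and `analyze` verbs is installed at
`inst/scripts/mepsc.R`.

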