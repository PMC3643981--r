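# binpursuit

Model-based spike sorting for multi-electrode extracellular recordings,
built around an explicit generative model: the recorded voltage is a
sparse linear superposition of per-neuron spatiotemporal spike waveforms
in correlated Gaussian background noise, with a Bernoulli prior over
binary spike trains. Spike trains are recovered by **binary pursuit**, a
greedy MAP algorithm that inserts and deletes spikes one at a time,
always taking the flip with the largest gain in log posterior.

It is written for electrophysiologists and methods developers who care
about the failure mode that conventional clustering sorters share: when
two nearby neurons fire near-synchronously, their waveforms sum, the
composite snippet falls outside every cluster, and the event is silently
dropped. Those misses are systematic — they delete precisely the
synchronous spikes, carving a spurious notch into the pair's
cross-correlogram and corrupting downstream correlation analyses.

## The model and the estimator

Voltage on `E` electrodes is modeled as

```
V(t) = sum_j sum_l W_j(l) X_j(t - l) + eps(t)
```

with `W_j` an `E x N_w` template, `X_j` in {0,1} per sample bin, and
`eps` Gaussian with space-time separable covariance. With the Bernoulli
prior `p_j` per bin, the negative log posterior in whitened coordinates
is

```
L(X) = 1/2 || V_w - W_w * X ||^2 + sum_j theta_j n_j,
theta_j = log((1 - p_j) / p_j),
```

which the package minimizes by coordinate ascent:

1. **Waveforms** — joint sparse Toeplitz least squares across neurons
   (overlaps are resolved, not averaged), then subset-selection pruning
   of sub-noise electrodes.
2. **Noise** — per-electrode temporal covariance (16-bin window) whitened
   by the central column of its inverse square root, then instantaneous
   spatial whitening across electrodes; waveforms re-fit in whitened
   space.
3. **Spikes** — binary pursuit in 1-s blocks: the gain of inserting
   neuron `j` at bin `t` is `w'r - ||w||^2/2 - theta_j` over the
   template's footprint; the globally best flip is applied and gains are
   refreshed only where footprints overlap, until no single flip helps.
   Each inserted spike is refined by a ridge-regularized first-order
   Taylor correction in spike time (sub-bin), amplitude and width.

Ground-truth-free diagnostics — the cross-correlogram artifact index
(missed-synchrony indicator), the refractory contamination rate
(false-positive indicator), and per-neuron prior-sensitivity analysis
with a power-law error calibration — quantify sorting quality, and a
bundled simulator generates recordings from exactly the model above with
known ground truth.

## Worked example

Simulate 20 s on 8 electrodes with four neurons at SNR 8, 10 spikes/s,
20% of neuron 1's spikes duplicated into neuron 2 (synchrony), sort, and
inspect:

```r
library(binpursuit)

sim <- simulate_recording(n_electrodes = 8, duration_s = 20,
                          n_neurons = 4, snr = 8, rates = 10,
                          sync_spec = list(list(pair = c(1, 2), prob = 0.2,
                                                jitter_bins = 0)),
                          seed = 42)
sim$recording
#> <bp_recording> 8 electrodes x 400000 samples @ 20000 Hz (20.00 s)

init <- cluster_init(sim$recording, bp_config(), k = 4, seed = 43)
init
#> <bp_init> 4 clusters, 645 assigned spikes (790 candidates)

fit <- coordinate_ascent(sim$recording, init$spikes, bp_config())
fit
#> <bp_fit> 810 spikes over 4 neurons; objective 1610816.62
```

The initializer assigned only 645 of 790 candidate events — the rest are
mostly overlap composites it deliberately rejects — while the MAP solver
recovers 810 spikes against 811 in the ground truth (total error rate
0.12% after matching neurons up to permutation with
`aligned_spike_times()` + `match_spikes()`). Diagnostics:

```r
contamination <- sapply(1:4, function(j)
  contamination_rate(fit$spikes, refractory_ms = 1.5, duration_s = 20,
                     neuron_id = j))
round(contamination, 2)
#> [1] 44.75  0.00  0.00  0.00
```

Neuron 1 of the fit is the synchrony *target* train: the generator
injects coincident spikes after refractory enforcement, so its ground
truth genuinely contains refractory violations — and the estimate
reproduces the true contamination (44.76%) to 0.01 points, while the
other neurons are clean. The artifact index of the synchronized pair's
cross-correlogram is strongly negative for the sorted trains (a genuine
zero-lag synchrony peak, not a notch); computed on the initializer's
trains instead, it is large and positive — the clustering artifact that
binary pursuit repairs.

## Layout

- `R/simulator.R` — generative-model simulator (templates, Bernoulli
  trains with refractoriness and synchrony, separable AR(1) x spatial
  noise)
- `R/cluster_init.R` — detection, snippets, PCA, curated k-means
  initializer
- `R/waveforms.R` — Toeplitz regression, pruning, derivative tensors
- `R/whitening.R` — residual-based two-stage separable whitening
- `R/binary_pursuit.R` — the greedy MAP solver, variability correction,
  block processing, coordinate-ascent driver
- `R/diagnostics.R` — CCFs, artifact index, contamination, matching,
  sensitivity, power-law calibration, scalar detection simulation
- `R/io.R` — float32+JSON recordings, TSV event tables, pipeline runner
- `vignettes/binary-pursuit-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
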