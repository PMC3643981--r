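---
title: "Model-based spike sorting by binary pursuit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based spike sorting by binary pursuit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(binpursuit)
```

## The generative model

`binpursuit` treats multi-electrode extracellular voltage as a sparse
linear superposition of spike waveforms in correlated Gaussian noise:

$$V(t) \;=\; \sum_{j=1}^{J} \sum_{\ell=1}^{N_w} W_j(\ell)\, X_j(t-\ell)
\;+\; \varepsilon(t),$$

where $W_j$ is neuron $j$'s spatiotemporal template (electrodes x taps),
$X_j$ a binary spike train on the sample lattice, and $\varepsilon$
zero-mean Gaussian noise with a space-time separable covariance. A
Bernoulli prior with per-bin spike probability $p_j$ completes the model;
its negative log gives each inserted spike a penalty
$\theta_j = \log\frac{1-p_j}{p_j}$. After whitening, the negative log
posterior is

$$L(X) = \tfrac12 \lVert \bar V - \bar W * X \rVert^2 +
\sum_j \theta_j\, n_j ,$$

with $n_j$ the spike count of neuron $j$ and bars denoting whitened
quantities. The sorter is a coordinate-ascent MAP estimator: linear
regression for $W$ given $X$, greedy binary optimization ("binary
pursuit") for $X$ given $W$.

Why model superposition at all? Clustering-based sorters implicitly
assume spikes arrive in isolation. When two nearby neurons fire within a
waveform's span, the recorded snippet is the *sum* of two templates, falls
far from both clusters in feature space, and is discarded as an outlier.
The resulting misses are not random: they delete precisely the
near-synchronous events, carving a spurious notch at zero lag into the
pair's cross-correlogram and biasing any downstream correlation analysis.
The explicit superposition model removes this artifact because inserting
one spike explains only its own template's footprint, leaving the
partner's energy in the residual to be claimed next.

## The greedy solver

Binary pursuit starts from the empty lattice and repeatedly flips the
single (neuron, bin) entry with the largest gain in log posterior.
Inserting a spike at bin $t$ changes $L$ by

$$\Delta L_j(t) = \bar w_j^\top r_{[t]} - \tfrac12 \lVert \bar w_j
\rVert^2 - \theta_j,$$

using only the residual $r$ inside the template's footprint; deleting an
existing spike is the mirror image. The solver maintains the correlation
surface $b_j(t) = \bar w_j^\top r_{[t]}$ (computed per block with one
delay-embedding matrix product per electrode) and, after each flip,
refreshes it only on the bins whose footprints overlap the flipped
template. Each accepted flip strictly decreases $L$; since $L$ is bounded
below and the state space finite, termination is guaranteed, at a
configuration where no single insertion or deletion improves the
objective by more than the tolerance (`tol_frac` x the largest squared
template norm, default 1e-9). Ties in the gain surface break toward the
lowest neuron id, then the lowest bin, making runs bit-reproducible.

Blocks: data are processed in `block_s` = 1 s blocks. Each block is
solved on data padded by one template length on both sides, but only
events whose bin falls inside the block's own zone are reported. A spike
straddling a boundary is therefore recovered by exactly one block (the
one owning its bin, which sees the full waveform in its pad), and no
cross-block deduplication pass is needed; results for isolated spikes are
independent of the block size.

## Waveform estimation, pruning, whitening

Given spike trains, templates are the least-squares solution of the
sparse Toeplitz regression $V \approx X W$, solved jointly across
neurons per electrode so temporally overlapping spikes are resolved
rather than averaged into each other. The normal equations carry a tiny
diagonal jitter (1e-10 x the mean diagonal) purely for numerical
robustness; exactly identical spike trains are detected beforehand and
reported as a rank-deficiency error naming the neurons.

Pruning zeroes a (neuron, electrode) waveform whose vector norm falls
below `prune_a` (default 1) times that electrode's robust noise scale
(MAD-based). This sparsifies templates without biasing large ones and
shrinks every footprint the solver must update.

Noise whitening is two-stage and separable, estimated from
spike-subtracted residuals: per-electrode temporal covariance over a
16-bin (0.8 ms at 20 kHz) window, symmetrized to Toeplitz form, with the
FIR whitening filter taken as the central column of its inverse square
root; then the instantaneous spatial covariance across electrodes
(estimated on temporally whitened residuals subsampled every 16 bins to
suppress serial dependence), whitened by its inverse matrix square root.
Matrix inverse square roots use a symmetric eigendecomposition with an
eigenvalue floor of 1e-8 x the largest eigenvalue. Edge samples (the
first/last 16 bins) are filtered with truncated filters and flagged.
Waveforms are then re-fit in the whitened space so the unit-variance
objective holds exactly. The separability assumption is quantified in the
test suite against a dense Kronecker-covariance oracle on small
instances.

## Sub-bin variability correction

True spike times are not lattice-aligned, and spike amplitude and width
vary (e.g. during bursts). Each inserted spike is therefore refined by a
first-order Taylor model

$$w(\tau, a, \sigma) \approx \bar w + \tau\, d_{\text{time}} +
a\, d_{\text{amp}} + \sigma\, d_{\text{width}},$$

whose coefficients solve a ridge regression
$(D^\top D + \gamma I)^{-1} D^\top r$ against the post-insertion
residual; the projection matrix is precomputed per neuron. Derivatives
are computed numerically from the cubic-spline-interpolated template:
$d_{\text{amp}}$ is the template itself, $d_{\text{time}}$ a central
difference under time shift (step `delta` = 0.1 bins), and
$d_{\text{width}}$ a central difference under time dilation anchored at
the alignment peak, so a width change does not move the peak. The spline
extrapolates smoothly within one tap of the window edges (a hard zero
there would make edge derivatives blow up as the difference step
shrinks).

Defaults: only the temporal derivative is enabled (it dominates the
benefit and avoids opening the door to false positives through extra
flexibility); coefficients are clamped to |0.5|;
$\gamma$ = 0.1 x trace$(D^\top D)$/ncol$(D)$. A clamped correction that
would increase the residual norm is dropped so descent is never violated.
Deletions restore exactly the waveform that was subtracted (canonical
plus correction), keeping the residual bookkeeping bit-exact. Estimated
times are `(bin + subbin_offset) / rate`; when comparing against spike
sets expressed in a different alignment convention, use
`aligned_spike_times()`, which references each neuron's waveform trough.

## Prior calibration

The plug-in prior $p_j = n_j/N$ from the initializer underestimates the
penalty needed in practice: sorting with it inflates the refractory
contamination rate. The per-spike penalty is therefore scaled by
`prior_multiplier`, default 6, the factor at which the miss indicator
(CCF artifact) and the false-positive indicator (contamination) are
jointly below their clustering baselines. The multiplier is the natural
lever of the miss/false-positive trade-off: raising it weakly decreases
the spike count (a tested invariant), and per-neuron sensitivity of the
count to this multiplier is itself a quality diagnostic (below).

## The clustering initializer

The MAP machinery needs an initial estimate of the neuron count, spike
trains and firing rates. The initializer is conventional: per-electrode
threshold detection at `threshold_multiplier` = 4 robust noise SDs
(MAD/0.6745), candidate deduplication within one window, snippet
extraction over a 1.5 ms window and the 6 nearest electrodes
(peak-aligned at the window center, embedded in a fixed global
electrodes x taps frame so all events share one feature space), PCA to
`n_dims` = 5, and seeded k-means.

Overlapping spikes are the known failure mode, and the initializer is
*meant* to exhibit it (the solver's value is repairing it), but it must
not hallucinate: synchronous pairs produce dense clusters of summed
waveforms that k-means happily adopts as extra "neurons", stealing
cluster budget and biasing the regression. Three measures keep the
initial model clean, substituting for the human oversight that would
otherwise curate cluster counts:

1. the data are over-clustered (k + max(4, k) groups), and subclusters
   whose raw-snippet centroids agree up to a time shift are merged back
   (detection jitter splits one neuron into shifted copies);
2. clusters whose centroid is well explained as a shifted *sum* of two
   other centroids (coefficients in [0.6, 1.4], relative residual
   < 0.3) are discarded wholesale — these are the composite clusters;
   the k largest survivors become the neurons;
3. remaining points farther than a robust Mahalanobis radius
   (median/MAD per dimension, default sqrt of the 0.99 chi-square
   quantile) from every cluster are left unassigned. The robust scale
   matters: a plain covariance is inflated by the very composite events
   it should reject.

Isolated-spike label purity is essentially perfect in the tested regimes;
the deliberately unassigned events (overlaps, plus a few percent of
false rejections from the heavy-tailed robust distance) are recovered by
the solver.

## Diagnostics without ground truth

* **Cross-correlogram (CCF)**: conditional rate of train b around each
  spike of train a. The **artifact index** is (mean flank rate at
  1-5 ms) minus (mean rate within +-1 ms), over the baseline rate —
  positive when near-synchronous spikes are missing. Window edges are
  configurable; the flank baseline can be switched to the far-flank mean.
* **Contamination rate**: the rate of spikes inside another spike's
  refractory window over the rate outside, occupancy-corrected
  (in-window counts divided by the union length of all windows), in
  percent. A Poisson train scores ~100%, a perfectly refractory train 0%.
  Default refractory window 1.5 ms, configurable.
* **Prior sensitivity**: |d log(count) / d log(multiplier)| at the
  default multiplier, computed by a central difference over the
  neighboring multipliers of a grid spanning one decade. Well-isolated
  units are flat (sensitivity near 0); poorly isolated units are steep.
  On simulated populations the log-log regression of true error rate on
  sensitivity is the calibration that lets sensitivity, which needs no
  ground truth, predict error rates on real data.
* **Spike matching**: one-to-one matching within +-0.5 ms by sorted
  two-pointer pairing (optimal for interval matching on a line; verified
  against a brute-force assignment oracle), giving hits, misses, false
  positives and error rate = (misses + false positives)/true count.

The refractory period is *not* enforced by the solver — faithful to the
model, which treats bins independently — so contamination remains a
meaningful independent error indicator.

## What the simulator emulates, and what it does not

`simulate_recording()` draws from exactly the model above: biphasic
gamma-difference templates (default 30 taps = 1.5 ms at 20 kHz; sharp
~0.4 ms trough peaking about a quarter into the window, slower rebound
decaying to zero by the window end), exponential spatial amplitude decay
(`lambda` = 1.2 electrode pitches), Bernoulli trains with refractory
deletion (later spike of a violating pair removed), optional pairwise
synchrony injected by copying spikes of a master train with uniform
jitter, and separable noise: AR(1) in time (default coefficient 0.3)
mixed spatially by the matrix square root of an exponential correlation
(default length 0.5 pitches), unit variance. SNR is defined as peak
template amplitude over the marginal noise SD.

The noise and shape defaults were calibrated once so that the *whitened*
template energy at nominal SNR 8 (roughly 240 in unit-noise energy) puts
SNR 8 in the well-isolated regime — i.e. nominal SNR tracks effective
detectability. Waveforms that are smooth and spatially diffuse in the
same way as the background noise lose a large fraction of their energy
to whitening, which would silently turn a nominally high-SNR simulation
into a marginal-detection one; the sharp trough (high-frequency content)
and a signal spatial scale distinct from the noise correlation length
avoid that degeneracy, and are also the physically realistic choice.

Ground-truth sub-bin offsets (`subbin_jitter = TRUE`) are drawn uniform
in (-0.5, 0.5) bins and applied through the same first-order Taylor
expansion the solver uses. That makes sub-bin recovery a well-posed
estimation problem with a known quantization floor (RMSE
$1/\sqrt{12} \approx 0.29$ bins without the correction), but it also
means the simulator does not probe the Taylor approximation error of
large true shifts. Other real-data features deliberately not emulated:
heavy-tailed (spike-like) background noise, electrode drift,
burst-dependent amplitude dynamics beyond the linear term, and
non-separable noise. Passing tests therefore demonstrate correctness of
the estimator under its own model assumptions, plus robustness to the
initializer's failure modes — not performance on tissue.

Study-condition sizes used by the test suite (chosen as desk-scale
stand-ins for the original array recordings): the synchrony-repair
scenario uses 8 electrodes x 6 neurons x 60 s at 20 kHz with 20%
pairwise synchrony; oracle-equivalence and descent checks run on
4-neuron x 2000-bin instances; the sensitivity/error calibration uses 20
single-neuron recordings of 30 s spanning SNR 5-9.5; whitening flatness
uses 2e5-sample noise fields.

## Numerical and design choices worth knowing

* Bins are 0-based; an event's `bin` is where waveform tap 1 sits; times
  in seconds are `(bin + subbin_offset)/rate`.
* `estimate_temporal_cov` shrinks a non-positive-definite banded estimate
  toward its diagonal in 5% steps (logged) until positive definite.
* Coordinate ascent defaults to a single round — the regime in which the
  algorithm is typically operated — but supports more; from round two
  onward the noise model, prior and support mask are frozen so the
  objective is measured in one fixed metric and the recorded trace is
  guaranteed non-increasing (re-estimating the metric each round would
  make the trace incomparable across rounds).
* The prior probability p is clamped to [1/N, 0.499] before the log-odds;
  theta(0.5) = 0 is allowed.
* k (the neuron count) is user-supplied where known (simulations) or
  chosen by mean silhouette over a configured range; this is an
  automated stand-in for expert curation and is the least robust part of
  the pipeline on messy data.
* The sensitivity/error power-law calibration floors zero error rates
  and zero sensitivities at half-count quantization levels
  (0.5/n spikes) so the log-log fit is defined; floored points sit at
  the calibration's resolution limit by construction.
* The spatial-spread and synchrony-generation recipes are stand-ins: the
  field has no agreed forward model for either, so the exponential decay
  and copy-with-jitter choices here should be treated as simulation
  conveniences, not biophysics.

## Known limitations

Waveform drift and non-stationary noise are out of scope. The greedy
solver finds a local optimum only; its characteristic failure is
explaining an overlap with a wrongly placed spike when templates are
nearly collinear. Neuron-count selection is heuristic. The contamination
estimator assumes a single refractory window per spike and the CCF
baseline uses the partner train's mean rate (a far-flank baseline is
available as an option).
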