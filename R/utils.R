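#' Convert a duration in milliseconds to a number of sample bins
#'
#' @param ms duration in milliseconds.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param round_fn rounding applied to the fractional bin count
#'   (default [base::round]).
#' @return integer number of bins.
#' @examples
#' ms_to_bins(1.5, 20000)  # 30 samples per 1.5 ms action potential
#' ms_to_bins(0.8, 20000)  # 16-bin noise-covariance window
#' @export
ms_to_bins <- function(ms, sampling_rate_hz, round_fn = round) {
  stopifnot(is.finite(ms), ms >= 0, sampling_rate_hz > 0)
  as.integer(round_fn(ms * sampling_rate_hz / 1000))
}

#' Width of one sample bin in milliseconds
#'
#' The spike-time lattice spacing: at 20 kHz each bin spans 0.05 ms.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @return bin width in ms.
#' @export
bin_spacing_ms <- function(sampling_rate_hz) {
  stopifnot(sampling_rate_hz > 0)
  1000 / sampling_rate_hz
}

#' Expected inter-spike interval in bins for a Bernoulli spike train
#'
#' A neuron firing at `rate_hz` under per-bin spike probability
#' p = rate/sampling rate emits on average one spike every 1/p bins
#' (e.g. one per 500 bins at 40 spikes/s sampled at 20 kHz).
#'
#' @param rate_hz firing rate, spikes/s.
#' @param sampling_rate_hz sampling rate, Hz.
#' @return expected ISI in bins.
#' @export
expected_isi_bins <- function(rate_hz, sampling_rate_hz) {
  stopifnot(rate_hz > 0, sampling_rate_hz > rate_hz)
  sampling_rate_hz / rate_hz
}

#' Number of scalar samples processed per block
#'
#' Block processing flattens each block into a single vector of
#' n_electrodes x (block_s x sampling rate) samples.
#'
#' @param n_electrodes electrode count.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param block_s block duration, seconds.
#' @return scalar sample count per block.
#' @export
block_vector_length <- function(n_electrodes, sampling_rate_hz, block_s = 1.0) {
  stopifnot(n_electrodes >= 1, sampling_rate_hz > 0, block_s > 0)
  n_electrodes * sampling_rate_hz * block_s
}

# Symmetric matrix inverse square root with eigenvalue flooring.
# floor_frac * max(eigenvalue) guards rank deficiency.
mat_inv_sqrt <- function(S, floor_frac = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, floor_frac * max(e$values))
  e$vectors %*% (t(e$vectors) / sqrt(lam))
}

mat_sqrt <- function(S, floor_frac = 1e-12) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(lam))
}

# Toeplitz matrix from a first-column vector.
toeplitz_sym <- function(v) stats::toeplitz(v)

# Evaluate with a temporary RNG seed, restoring RNG state afterwards.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
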