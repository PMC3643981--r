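# Two-stage separable noise whitening: per-electrode temporal whitening by
# the central column of the inverse square root of a banded Toeplitz
# autocovariance, followed by instantaneous spatial whitening across
# electrodes. After whitening, the likelihood is an unweighted sum of
# squares with unit noise variance.

#' Residual of a recording under the current spike/waveform model
#'
#' residual = V - sum_j W_j * X_j, the exact subtraction of the model
#' prediction (including any per-event Taylor coefficients carried by the
#' events, if derivative tensors are present).
#'
#' @param recording a [new_recording()].
#' @param waveforms a [waveform_set()].
#' @param spikes a [spike_events()] set.
#' @return electrodes x samples residual matrix.
#' @export
compute_residual <- function(recording, waveforms, spikes) {
  recording$data - predict_voltage(waveforms, spikes, recording$n_samples)
}

#' Estimate per-electrode temporal noise covariance and whitening filter
#'
#' Banded autocovariance over a `window_bins` window (default 16 bins,
#' 0.8 ms at 20 kHz), symmetrized into Toeplitz form per electrode. The
#' whitening filter is the central column of the matrix inverse square
#' root. A non-positive-definite estimate is shrunk toward its diagonal
#' until positive definite (logged as a message).
#'
#' @param residual electrodes x samples matrix of spike-subtracted
#'   residuals.
#' @param window_bins covariance window length in bins.
#' @return list with per-electrode `temporal_cov` (list of Toeplitz
#'   matrices) and `temporal_filter` (window_bins x electrodes matrix; the
#'   filter center is tap `window_bins/2`).
#' @export
estimate_temporal_cov <- function(residual, window_bins = 16) {
  if (!is.matrix(residual)) residual <- matrix(residual, nrow = 1)
  E <- nrow(residual)
  stopifnot(ncol(residual) > 10 * window_bins)
  covs <- vector("list", E)
  filt <- matrix(0, window_bins, E)
  center <- window_bins %/% 2
  for (e in seq_len(E)) {
    ac <- stats::acf(residual[e, ], lag.max = window_bins - 1,
                     type = "covariance", plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    Ct <- toeplitz_sym(ac)
    shrink <- 0
    while (min(eigen(Ct, symmetric = TRUE, only.values = TRUE)$values) <=
           1e-12 * Ct[1, 1]) {
      shrink <- shrink + 0.05
      Ct <- (1 - shrink) * toeplitz_sym(ac) + shrink * diag(ac[1], window_bins)
      if (shrink >= 1) break
    }
    if (shrink > 0)
      message(sprintf("electrode %d: temporal covariance shrunk by %.2f", e,
                      shrink))
    covs[[e]] <- Ct
    filt[, e] <- mat_inv_sqrt(Ct)[, center]
  }
  list(temporal_cov = covs, temporal_filter = filt, center = center,
       window_bins = window_bins)
}

# Apply a centered FIR filter to each electrode row. Taps m = 1..K act on
# x[t + m - center]; edge samples use the truncated filter.
fir_filter_centered <- function(X, filters, center) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  K <- nrow(filters)
  T_ <- ncol(X)
  pad <- K
  Y <- matrix(0, nrow(X), T_)
  for (e in seq_len(nrow(X))) {
    xp <- c(numeric(pad), X[e, ], numeric(pad))
    acc <- numeric(T_)
    for (m in seq_len(K)) {
      off <- m - center
      acc <- acc + filters[m, e] * xp[pad + off + seq_len(T_)]
    }
    Y[e, ] <- acc
  }
  Y
}

#' Temporally whiten a voltage matrix
#'
#' FIR-filters each electrode with its temporal whitening filter (central
#' column of the inverse square root of the temporal covariance). The
#' first/last `window_bins` samples are filtered with truncated filters and
#' flagged in the `edge_bins` attribute.
#'
#' @param X electrodes x samples matrix.
#' @param tc result of [estimate_temporal_cov()].
#' @return whitened matrix with attribute `edge_bins`.
#' @export
temporal_whiten <- function(X, tc) {
  Y <- fir_filter_centered(X, tc$temporal_filter, tc$center)
  attr(Y, "edge_bins") <- tc$window_bins
  Y
}

#' Estimate the instantaneous spatial covariance across electrodes
#'
#' Estimated from temporally whitened residuals, subsampled every
#' `stride` bins to reduce serial dependence.
#'
#' @param residual_w temporally whitened residual matrix.
#' @param stride subsampling stride in bins (default: the temporal window).
#' @return electrodes x electrodes covariance matrix.
#' @export
estimate_spatial_cov <- function(residual_w, stride = 16) {
  idx <- seq(stride, ncol(residual_w) - stride, by = stride)
  R <- residual_w[, idx, drop = FALSE]
  tcrossprod(R) / length(idx)
}

#' Spatially whiten a voltage matrix
#'
#' Multiplies the vector of data in each time bin by the inverse square
#' root of the spatial covariance, making the instantaneous covariance
#' approximately the identity.
#'
#' @param X electrodes x samples matrix.
#' @param spatial_cov electrodes x electrodes positive-definite covariance.
#' @return whitened matrix.
#' @export
spatial_whiten <- function(X, spatial_cov) {
  if (nrow(X) != nrow(spatial_cov)) stop("dimension mismatch")
  mat_inv_sqrt(spatial_cov) %*% X
}

#' Full two-stage whitening pipeline
#'
#' Estimates the noise model from spike-subtracted residuals, whitens the
#' recording temporally then spatially, and re-estimates (and optionally
#' re-prunes) the waveforms in the whitened space so the MAP objective
#' holds with unit noise variance.
#'
#' @param recording a [new_recording()] (raw).
#' @param spikes current spike estimate.
#' @param waveforms current waveforms (raw space), used for the residual.
#' @param window_bins temporal covariance window.
#' @param prune_a pruning constant applied to the re-estimated whitened
#'   waveforms (NULL to skip pruning).
#' @return list with `recording_w` (whitened [new_recording()]),
#'   `waveforms_w` (whitened, re-fit [waveform_set()]), and `noise_model`
#'   (class `bp_noise_model`).
#' @export
whiten_pipeline <- function(recording, spikes, waveforms,
                            window_bins = 16, prune_a = 1) {
  resid <- compute_residual(recording, waveforms, spikes)
  tc <- estimate_temporal_cov(resid, window_bins)
  Vt <- temporal_whiten(recording$data, tc)
  Rt <- temporal_whiten(resid, tc)
  Cs <- estimate_spatial_cov(Rt, stride = window_bins)
  Ws <- mat_inv_sqrt(Cs)
  Vw <- Ws %*% Vt
  rec_w <- new_recording(Vw, recording$sampling_rate_hz, recording$geometry)
  wf_w <- estimate_waveforms(rec_w, spikes, taps = waveforms$taps,
                             support_mask = waveforms$support_mask)
  if (!is.null(prune_a))
    wf_w <- prune_waveforms(wf_w, noise_scale = 1, a = prune_a)
  nm <- structure(list(temporal_cov = tc$temporal_cov,
                       temporal_filter = tc$temporal_filter,
                       center = tc$center, window_bins = window_bins,
                       spatial_cov = Cs, spatial_whitener = Ws),
                  class = "bp_noise_model")
  list(recording_w = rec_w, waveforms_w = wf_w, noise_model = nm)
}

#' @export
print.bp_noise_model <- function(x, ...) {
  cat(sprintf("<bp_noise_model> %d electrodes, %d-bin temporal window\n",
              nrow(x$spatial_cov), x$window_bins))
  invisible(x)
}

#' Apply a fitted noise model to new data
#'
#' @param X electrodes x samples matrix.
#' @param noise_model a `bp_noise_model` from [whiten_pipeline()].
#' @return whitened matrix.
#' @export
apply_whitening <- function(X, noise_model) {
  Vt <- fir_filter_centered(X, noise_model$temporal_filter,
                            noise_model$center)
  noise_model$spatial_whitener %*% Vt
}
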