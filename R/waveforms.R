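# Waveform estimation: joint least squares over all neurons per electrode
# (resolving overlaps), subset-selection pruning, and the derivative
# tensors (time shift, amplitude, width dilation) used by the Taylor
# variability correction.

#' Estimate spike waveforms by least squares
#'
#' Solves V ~ X W per electrode, where X is the sparse Toeplitz design
#' built from all neurons' binary spike trains jointly, so temporally
#' overlapping spikes are resolved by the regression. Minimizes the
#' quadratic data term under unit (identity) noise covariance.
#'
#' @param recording a [new_recording()] (raw or whitened).
#' @param spikes a [spike_events()] set (integer bins used; sub-bin
#'   coefficients are ignored by the regression).
#' @param taps waveform length in taps.
#' @param support_mask optional neurons x electrodes logical matrix;
#'   electrodes outside the mask are fixed at zero.
#' @param jitter diagonal regularizer added to the normal equations as
#'   `jitter * mean(diag)`, for robustness to near-singularity.
#' @return a [waveform_set()].
#' @export
estimate_waveforms <- function(recording, spikes, taps = 30,
                               support_mask = NULL, jitter = 1e-10) {
  ev <- spikes$events
  J <- spikes$n_neurons
  E <- recording$n_electrodes
  T_ <- recording$n_samples
  stopifnot(taps >= 1, spikes$n_bins <= T_)
  counts <- tabulate(ev$neuron_id, J)
  if (any(counts == 0))
    stop("every neuron needs at least one spike; neurons without spikes: ",
         paste(which(counts == 0), collapse = ", "))
  # identical spike trains make the design exactly singular
  keys <- vapply(seq_len(J), function(j)
    paste(ev$bin[ev$neuron_id == j], collapse = ","), "")
  if (anyDuplicated(keys)) {
    dup <- which(keys %in% keys[duplicated(keys)])
    stop("rank-deficient design: neurons with identical spike trains: ",
         paste(dup, collapse = ", "))
  }
  ok <- ev$bin + taps <= T_
  ev <- ev[ok, , drop = FALSE]
  # sparse design: column (j-1)*taps + l is neuron j's train delayed l-1
  i_idx <- rep(ev$bin, each = taps) + seq_len(taps)        # sample (1-based)
  j_idx <- rep((ev$neuron_id - 1L) * taps, each = taps) + seq_len(taps)
  X <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                            dims = c(T_, J * taps))
  XtX <- as.matrix(Matrix::crossprod(X))
  XtV <- as.matrix(Matrix::crossprod(X, t(recording$data)))  # (J*taps) x E
  diag(XtX) <- diag(XtX) + jitter * mean(diag(XtX))
  W <- tryCatch(solve(XtX, XtV), error = function(e)
    stop("singular waveform regression: ", conditionMessage(e)))
  tmpl <- array(0, c(J, E, taps))
  for (j in seq_len(J))
    tmpl[j, , ] <- t(W[(j - 1L) * taps + seq_len(taps), , drop = FALSE])
  if (!is.null(support_mask)) {
    for (j in seq_len(J)) tmpl[j, !support_mask[j, ], ] <- 0
  } else {
    support_mask <- matrix(TRUE, J, E)
  }
  waveform_set(tmpl, support_mask = support_mask)
}

#' Prune waveforms by subset selection on per-electrode norms
#'
#' Zeroes the waveform of neuron j on electrode e iff its vector norm
#' falls below `a` times the noise scale of that electrode, inducing
#' spatial sparsity without biasing large-amplitude waveforms. Idempotent.
#'
#' @param waveforms a [waveform_set()].
#' @param noise_scale per-electrode noise standard deviation (length
#'   n_electrodes, or scalar).
#' @param a non-negative pruning constant (default 1).
#' @return the pruned [waveform_set()] with updated support mask.
#' @export
prune_waveforms <- function(waveforms, noise_scale, a = 1) {
  if (a < 0) stop("pruning constant a must be >= 0")
  wf <- waveforms
  noise_scale <- rep_len(noise_scale, wf$n_electrodes)
  norms <- sqrt(apply(wf$templates^2, c(1, 2), sum))
  drop <- sweep(norms, 2, a * noise_scale, `<`)
  for (j in seq_len(wf$n_neurons)) wf$templates[j, drop[j, ], ] <- 0
  wf$support_mask <- wf$support_mask & !drop
  if (!is.null(wf$derivatives)) {
    for (nm in names(wf$derivatives))
      for (j in seq_len(wf$n_neurons))
        wf$derivatives[[nm]][j, drop[j, ], ] <- 0
  }
  wf
}

# cubic-interpolated evaluation of a tap series at fractional positions;
# the natural spline extrapolates smoothly within one tap of the edges
# (sub-bin shifts never look further), zero beyond.
interp_taps <- function(w, at, pad = 1) {
  f <- stats::splinefun(seq_along(w), w, method = "natural")
  out <- f(at)
  out[at < 1 - pad | at > length(w) + pad] <- 0
  out
}

#' Numerical waveform derivatives for the variability correction
#'
#' Computes, per neuron and electrode:
#' * `d_amp`: the template itself (derivative w.r.t. an amplitude scale),
#' * `d_time`: central finite difference of the cubic-interpolated
#'   template under a time shift (positive coefficient = spike later),
#' * `d_width`: central difference under time dilation about the alignment
#'   peak, so a width change does not move the peak.
#'
#' @param waveforms a [waveform_set()] with taps >= 8.
#' @param delta finite-difference step in bins (0 < delta <= 0.5).
#' @return the waveform set with `derivatives` populated.
#' @export
compute_derivatives <- function(waveforms, delta = 0.1) {
  wf <- waveforms
  stopifnot(wf$taps >= 8, delta > 0, delta <= 0.5)
  L <- wf$taps
  peak <- wf$alignment_tap
  d_time <- d_width <- array(0, dim(wf$templates))
  grid <- seq_len(L)
  for (j in seq_len(wf$n_neurons)) {
    for (e in seq_len(wf$n_electrodes)) {
      w <- wf$templates[j, e, ]
      if (all(w == 0)) next
      # w(l - tau): shift right for positive tau
      d_time[j, e, ] <- (interp_taps(w, grid - delta) -
                         interp_taps(w, grid + delta)) / (2 * delta)
      # dilation about the peak: w(peak + (l - peak)/(1 + sigma))
      wid_p <- interp_taps(w, peak + (grid - peak) / (1 + delta))
      wid_m <- interp_taps(w, peak + (grid - peak) / (1 - delta))
      d_width[j, e, ] <- (wid_p - wid_m) / (2 * delta)
    }
  }
  wf$derivatives <- list(d_time = d_time, d_amp = wf$templates,
                         d_width = d_width)
  wf
}

# prediction sum_j W_j * X_j as an electrodes x samples matrix
predict_voltage <- function(waveforms, spikes, n_samples = spikes$n_bins) {
  wf <- waveforms
  E <- wf$n_electrodes; L <- wf$taps
  V <- matrix(0, E, n_samples)
  ev <- spikes$events
  has_coefs <- nrow(ev) > 0 && any(abs(as.matrix(ev[3:5])) > 0) &&
    !is.null(wf$derivatives)
  for (i in seq_len(nrow(ev))) {
    j <- ev$neuron_id[i]; b <- ev$bin[i]
    if (b + L > n_samples) next
    w <- matrix(wf$templates[j, , ], E, L)
    if (has_coefs)
      w <- w + ev$subbin_offset[i] * matrix(wf$derivatives$d_time[j, , ], E, L) +
        ev$amp_coef[i] * matrix(wf$derivatives$d_amp[j, , ], E, L) +
        ev$width_coef[i] * matrix(wf$derivatives$d_width[j, , ], E, L)
    idx <- (b + 1):(b + L)
    V[, idx] <- V[, idx] + w
  }
  V
}
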