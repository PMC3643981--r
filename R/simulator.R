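# Ground-truth simulator implementing the same generative model the sorter
# assumes: V = sum_j W_j * X_j + Gaussian noise with separable space-time
# covariance; Bernoulli spike trains with refractoriness and injected
# pairwise synchrony.

#' Electrode grid geometry
#'
#' @param n number of electrodes.
#' @param pitch spacing between adjacent electrodes, grid units.
#' @param layout `"square"` or `"hex"` packing.
#' @return data.frame with columns `x`, `y`.
#' @export
electrode_grid <- function(n, pitch = 1, layout = c("square", "hex")) {
  layout <- match.arg(layout)
  stopifnot(n >= 1, pitch > 0)
  ncol_ <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  row <- i %/% ncol_
  col <- i %% ncol_
  x <- col * pitch
  y <- row * pitch
  if (layout == "hex") {
    x <- x + (row %% 2) * pitch / 2
    y <- y * sqrt(3) / 2
  }
  data.frame(x = x, y = y)
}

# Biphasic gamma-difference shape on a unit tap grid: a fast negative
# trough (peaking ~1/4 into the window, ~0.35 ms wide at 20 kHz/30 taps)
# followed by a slower positive rebound that decays to ~0 by the window
# end. Normalized so the global extremum is exactly -1 at one tap.
biphasic_shape <- function(taps, trough_peak_ratio = 0.4,
                           trough_pos = 0.18, trough_sharp = 8,
                           rebound_pos = 0.45, rebound_sharp = 6) {
  stopifnot(taps >= 4)
  t <- seq(0, 1, length.out = taps)
  g1 <- (t / trough_pos)^trough_sharp *
    exp(-trough_sharp * (t - trough_pos) / trough_pos)
  g2 <- (t / rebound_pos)^rebound_sharp *
    exp(-rebound_sharp * (t - rebound_pos) / rebound_pos)
  s <- -(g1 / max(g1)) + trough_peak_ratio * (g2 / max(g2))
  s / max(abs(s))
}

#' Build one neuron's spatiotemporal waveform
#'
#' The temporal shape is a biphasic gamma-difference template (negative
#' trough then positive rebound); amplitude on each electrode decays as
#' exp(-distance / lambda) from the neuron position. The peak sample on the
#' closest electrode equals `-amplitude` (negative-going convention).
#'
#' @param geometry electrode geometry (data.frame `x`, `y`).
#' @param position length-2 numeric, neuron location in grid units.
#' @param amplitude peak amplitude, voltage units; must be >= 0.
#' @param lambda spatial decay length, grid units.
#' @param taps number of time taps (default 30, ~1.5 ms at 20 kHz).
#' @param trough_peak_ratio amplitude of the positive rebound relative to
#'   the trough.
#' @return electrodes x taps matrix.
#' @export
make_waveform <- function(geometry, position, amplitude, lambda = 1,
                          taps = 30, trough_peak_ratio = 0.4) {
  geometry <- as.data.frame(geometry)
  stopifnot(nrow(geometry) >= 1, taps >= 4)
  pars <- c(position, amplitude, lambda, trough_peak_ratio)
  if (any(!is.finite(pars))) stop("non-finite waveform parameters")
  if (amplitude < 0) stop("amplitude must be >= 0")
  s <- biphasic_shape(taps, trough_peak_ratio)
  d <- sqrt((geometry$x - position[1])^2 + (geometry$y - position[2])^2)
  decay <- exp(-d / lambda)
  outer(amplitude * decay, s)
}

#' Sample Bernoulli spike trains with refractoriness and synchrony
#'
#' Independent Bernoulli draws per bin at p_j = rate_j / sampling rate;
#' then refractory enforcement (the later spike of any violating pair is
#' deleted); then synchrony injection: for each listed pair (a, b) every
#' spike of a duplicates into b with the given coincidence probability and
#' uniform integer jitter.
#'
#' @param rates spikes/s per neuron.
#' @param duration_s recording duration, seconds.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param refractory_ms refractory period, ms.
#' @param sync_spec optional list of lists with fields `pair` (length-2
#'   neuron ids), `prob` (coincidence probability in 0..1), `jitter_bins`.
#' @param seed RNG seed (identical seed, identical output).
#' @param reserve_tail_bins bins at the end of the recording kept free of
#'   spikes so a full waveform always fits (set to the waveform tap count).
#' @return a [spike_events()] set.
#' @export
sample_spike_trains <- function(rates, duration_s, sampling_rate_hz,
                                refractory_ms = 1.5, sync_spec = NULL,
                                seed, reserve_tail_bins = 30) {
  stopifnot(all(rates >= 0), refractory_ms >= 0, duration_s > 0)
  if (any(rates >= sampling_rate_hz))
    stop("rate must be below the sampling rate")
  if (!is.null(sync_spec)) {
    for (s in sync_spec)
      stopifnot(length(s$pair) == 2, s$prob >= 0, s$prob <= 1)
  }
  n_bins <- as.integer(round(duration_s * sampling_rate_hz))
  max_bin <- n_bins - as.integer(reserve_tail_bins)
  refrac_bins <- refractory_ms * sampling_rate_hz / 1000
  with_seed(seed, {
    trains <- lapply(seq_along(rates), function(j) {
      p <- rates[j] / sampling_rate_hz
      if (p == 0) return(integer())
      bins <- which(stats::runif(n_bins) < p) - 1L  # 0-based
      enforce_refractory(bins, refrac_bins)
    })
    if (!is.null(sync_spec)) {
      for (s in sync_spec) {
        a <- s$pair[1]; b <- s$pair[2]
        src <- trains[[a]]
        pick <- src[stats::runif(length(src)) < s$prob]
        jit <- s$jitter_bins %||% 0
        if (jit > 0)
          pick <- pick + sample.int(2L * jit + 1L, length(pick),
                                    replace = TRUE) - jit - 1L
        trains[[b]] <- sort(unique(c(trains[[b]], pick)))
      }
    }
    ev <- do.call(rbind, lapply(seq_along(trains), function(j) {
      bins <- trains[[j]]
      bins <- bins[bins >= 0 & bins <= max_bin]
      if (!length(bins)) return(NULL)
      data.frame(neuron_id = j, bin = bins)
    }))
    if (is.null(ev)) ev <- data.frame(neuron_id = integer(), bin = integer())
    spike_events(ev, n_bins = n_bins, n_neurons = length(rates),
                 sampling_rate_hz = sampling_rate_hz)
  })
}

# Keep a spike only if at least refrac_bins after the last kept spike.
enforce_refractory <- function(bins, refrac_bins) {
  if (length(bins) < 2 || refrac_bins <= 0) return(bins)
  keep <- logical(length(bins))
  keep[1] <- TRUE
  last <- bins[1]
  for (i in 2:length(bins)) {
    if (bins[i] - last >= refrac_bins) {
      keep[i] <- TRUE
      last <- bins[i]
    }
  }
  bins[keep]
}

#' Sample separable space-time Gaussian noise
#'
#' Temporal correlation by an AR(1) recursion per electrode; spatial
#' correlation by mixing with a matrix square root of the spatial
#' covariance exp(-distance / spatial_length). Marginal variance is
#' `variance` on every electrode.
#'
#' @param n_electrodes electrode count.
#' @param n_samples sample count.
#' @param geometry electrode geometry (required if `spatial_length > 0`).
#' @param ar_coef AR(1) coefficient, |ar_coef| < 1 (scalar or per
#'   electrode... scalar only; the spatial mixing requires a shared
#'   temporal kernel for exact separability).
#' @param spatial_length spatial correlation length in grid units; 0 means
#'   spatially independent noise.
#' @param variance marginal noise variance, (voltage units)^2.
#' @param seed RNG seed.
#' @return electrodes x samples noise matrix.
#' @export
sample_noise <- function(n_electrodes, n_samples, geometry = NULL,
                         ar_coef = 0, spatial_length = 0, variance = 1,
                         seed) {
  stopifnot(variance >= 0, length(ar_coef) == 1)
  if (abs(ar_coef) >= 1) stop("AR coefficient must lie inside the unit circle")
  if (variance == 0) return(matrix(0, n_electrodes, n_samples))
  with_seed(seed, {
    innov_sd <- sqrt(1 - ar_coef^2)
    Z <- matrix(stats::rnorm(n_electrodes * n_samples, sd = innov_sd),
                n_electrodes, n_samples)
    if (ar_coef != 0) {
      for (e in seq_len(n_electrodes))
        Z[e, ] <- stats::filter(Z[e, ], ar_coef, method = "recursive")
    }
    if (spatial_length > 0) {
      if (is.null(geometry)) stop("geometry required for spatial correlation")
      S <- spatial_correlation(geometry, spatial_length)
      Z <- mat_sqrt(S) %*% Z
    }
    sqrt(variance) * Z
  })
}

# Exponential spatial correlation matrix from electrode geometry.
spatial_correlation <- function(geometry, spatial_length) {
  D <- as.matrix(stats::dist(as.data.frame(geometry)[c("x", "y")]))
  exp(-D / spatial_length)
}

#' Render a recording from waveforms, spikes and noise
#'
#' V(t) = sum over events of the (optionally perturbed) waveform placed at
#' the event bin, plus noise. Per-event perturbations use the first-order
#' Taylor expansion w + tau d_time + a d_amp + sigma d_width with the
#' derivative tensors of [compute_derivatives()].
#'
#' @param waveforms a [waveform_set()] (derivatives required if any event
#'   carries nonzero coefficients).
#' @param spikes a [spike_events()] set.
#' @param noise electrodes x samples matrix (zeros for a noiseless render).
#' @param sampling_rate_hz sampling rate of the output recording.
#' @param geometry electrode geometry for the output recording.
#' @return a [new_recording()].
#' @export
render_recording <- function(waveforms, spikes, noise, sampling_rate_hz,
                             geometry) {
  wf <- waveforms
  ev <- spikes$events
  E <- wf$n_electrodes; L <- wf$taps
  stopifnot(nrow(noise) == E, ncol(noise) >= spikes$n_bins)
  V <- noise
  has_coefs <- nrow(ev) > 0 && any(abs(as.matrix(ev[3:5])) > 0)
  if (has_coefs && is.null(wf$derivatives))
    wf <- compute_derivatives(wf)
  for (i in seq_len(nrow(ev))) {
    j <- ev$neuron_id[i]; b <- ev$bin[i]
    if (b + L > ncol(V))
      stop(sprintf("spike at bin %d too close to recording end (taps=%d)",
                   b, L))
    w <- matrix(wf$templates[j, , ], E, L)
    if (has_coefs) {
      w <- w + ev$subbin_offset[i] * matrix(wf$derivatives$d_time[j, , ], E, L) +
        ev$amp_coef[i] * matrix(wf$derivatives$d_amp[j, , ], E, L) +
        ev$width_coef[i] * matrix(wf$derivatives$d_width[j, , ], E, L)
    }
    idx <- (b + 1):(b + L)
    V[, idx] <- V[, idx] + w
  }
  new_recording(V, sampling_rate_hz, geometry)
}

#' Simulate a complete recording with known ground truth
#'
#' Convenience wrapper: builds waveforms on a grid, samples spike trains
#' and noise, renders the voltage. SNR is defined as peak template
#' amplitude over the marginal noise standard deviation.
#'
#' @param n_electrodes,duration_s,sampling_rate_hz recording dimensions.
#' @param n_neurons number of neurons; positions are spread over the grid.
#' @param snr peak amplitude / noise sd, scalar or per neuron.
#' @param rates spikes/s, scalar or per neuron.
#' @param refractory_ms refractory period for the generator.
#' @param sync_spec synchrony specification, see [sample_spike_trains()].
#' @param ar_coef,spatial_length,noise_variance noise parameters, see
#'   [sample_noise()].
#' @param lambda spatial decay length of waveform amplitude.
#' @param taps waveform length in taps.
#' @param subbin_jitter if TRUE, ground-truth sub-bin offsets are drawn
#'   uniform in (-0.5, 0.5) bins and applied via the Taylor expansion.
#' @param layout electrode grid layout.
#' @param seed RNG seed.
#' @return list with `recording`, `waveforms`, `spikes` (ground truth),
#'   `geometry`, `noise_sd`.
#' @export
simulate_recording <- function(n_electrodes = 8, duration_s = 60,
                               sampling_rate_hz = 20000, n_neurons = 6,
                               snr = 8, rates = 10, refractory_ms = 1.5,
                               sync_spec = NULL, ar_coef = 0.3,
                               spatial_length = 0.5, noise_variance = 1,
                               lambda = 1.2, taps = 30,
                               subbin_jitter = FALSE,
                               layout = "square", seed) {
  geometry <- electrode_grid(n_electrodes, layout = layout)
  snr <- rep_len(snr, n_neurons)
  rates <- rep_len(rates, n_neurons)
  noise_sd <- sqrt(noise_variance)
  # neuron positions: cycle over electrodes with a small offset so each
  # neuron has a distinct dominant electrode
  tmpl <- array(0, c(n_neurons, n_electrodes, taps))
  for (j in seq_len(n_neurons)) {
    e0 <- ((j - 1) %% n_electrodes) + 1
    pos <- c(geometry$x[e0] + 0.15 * ((j - 1) %/% n_electrodes),
             geometry$y[e0] + 0.1 * ((j - 1) %/% n_electrodes))
    tmpl[j, , ] <- make_waveform(geometry, pos, amplitude = snr[j] * noise_sd,
                                 lambda = lambda, taps = taps,
                                 trough_peak_ratio = 0.35 + 0.05 * (j %% 3))
  }
  wf <- waveform_set(tmpl)
  wf <- compute_derivatives(wf)
  spikes <- sample_spike_trains(rates, duration_s, sampling_rate_hz,
                                refractory_ms = refractory_ms,
                                sync_spec = sync_spec, seed = seed,
                                reserve_tail_bins = taps)
  if (subbin_jitter) {
    spikes$events$subbin_offset <- with_seed(seed + 1L,
      stats::runif(nrow(spikes$events), -0.5, 0.5))
  }
  noise <- sample_noise(n_electrodes, spikes$n_bins, geometry,
                        ar_coef = ar_coef, spatial_length = spatial_length,
                        variance = noise_variance, seed = seed + 2L)
  rec <- render_recording(wf, spikes, noise, sampling_rate_hz, geometry)
  list(recording = rec, waveforms = wf, spikes = spikes,
       geometry = geometry, noise_sd = noise_sd)
}
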