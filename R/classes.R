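#' Construct a multi-electrode recording object
#'
#' Thin container for an electrodes x time voltage matrix plus sampling
#' metadata and electrode geometry.
#'
#' @param data numeric matrix, electrodes x samples.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param geometry data.frame with columns `x`, `y` (grid units), one row
#'   per electrode.
#' @return an object of class `bp_recording`.
#' @export
new_recording <- function(data, sampling_rate_hz, geometry) {
  stopifnot(is.matrix(data), is.numeric(data), sampling_rate_hz > 0)
  geometry <- as.data.frame(geometry)
  stopifnot(all(c("x", "y") %in% names(geometry)),
            nrow(geometry) == nrow(data))
  if (any(!is.finite(data))) stop("recording contains non-finite voltages")
  structure(
    list(data = data,
         sampling_rate_hz = sampling_rate_hz,
         geometry = geometry,
         n_electrodes = nrow(data),
         n_samples = ncol(data)),
    class = "bp_recording")
}

#' @export
print.bp_recording <- function(x, ...) {
  cat(sprintf("<bp_recording> %d electrodes x %d samples @ %g Hz (%.2f s)\n",
              x$n_electrodes, x$n_samples, x$sampling_rate_hz,
              x$n_samples / x$sampling_rate_hz))
  invisible(x)
}

#' Construct a spike event set
#'
#' Events live on a binary lattice: at most one event per (neuron, bin).
#' `bin` is 0-based: an event at bin b places waveform tap 1 at sample
#' b + 1. Spike times in seconds are (bin + subbin_offset) / sampling rate.
#'
#' @param events data.frame with columns `neuron_id`, `bin`, and optionally
#'   `subbin_offset`, `amp_coef`, `width_coef` (defaulted to 0).
#' @param n_bins total number of sample bins in the recording.
#' @param n_neurons number of neurons.
#' @param sampling_rate_hz sampling rate in Hz (optional, for time
#'   conversion).
#' @return an object of class `bp_spikes`.
#' @export
spike_events <- function(events, n_bins, n_neurons,
                         sampling_rate_hz = NA_real_) {
  events <- as.data.frame(events)
  for (col in c("subbin_offset", "amp_coef", "width_coef")) {
    if (is.null(events[[col]])) events[[col]] <- numeric(nrow(events))
  }
  if (nrow(events) == 0) {
    events <- data.frame(neuron_id = integer(), bin = integer(),
                         subbin_offset = numeric(), amp_coef = numeric(),
                         width_coef = numeric())
  }
  events <- events[c("neuron_id", "bin", "subbin_offset",
                     "amp_coef", "width_coef")]
  events$neuron_id <- as.integer(events$neuron_id)
  events$bin <- as.integer(events$bin)
  stopifnot(all(events$neuron_id >= 1), all(events$neuron_id <= n_neurons),
            all(events$bin >= 0), all(events$bin < n_bins))
  if (anyDuplicated(events[c("neuron_id", "bin")]))
    stop("duplicate (neuron, bin) events")
  if (any(!is.finite(as.matrix(events[3:5]))))
    stop("non-finite event coefficients")
  events <- events[order(events$neuron_id, events$bin), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, n_bins = as.integer(n_bins),
                 n_neurons = as.integer(n_neurons),
                 sampling_rate_hz = sampling_rate_hz),
            class = "bp_spikes")
}

#' @export
print.bp_spikes <- function(x, ...) {
  cat(sprintf("<bp_spikes> %d events, %d neurons, %d bins\n",
              nrow(x$events), x$n_neurons, x$n_bins))
  invisible(x)
}

#' Spike times in seconds
#'
#' @param spikes a `bp_spikes` object.
#' @param neuron_id optional neuron filter.
#' @return numeric vector of spike times (bin + subbin offset) / rate.
#' @export
spike_times <- function(spikes, neuron_id = NULL) {
  ev <- spikes$events
  if (!is.null(neuron_id)) ev <- ev[ev$neuron_id %in% neuron_id, ]
  if (is.na(spikes$sampling_rate_hz))
    stop("spike set has no sampling rate; cannot convert bins to seconds")
  sort((ev$bin + ev$subbin_offset) / spikes$sampling_rate_hz)
}

#' Construct a waveform set
#'
#' Houses per-neuron spatiotemporal templates (neurons x electrodes x taps),
#' the per-(neuron, electrode) support mask maintained by pruning, the
#' alignment tap (canonical negative peak), and optional derivative tensors
#' used by the Taylor variability correction.
#'
#' @param templates numeric array, neurons x electrodes x taps.
#' @param alignment_tap tap index (1-based) of the canonical peak.
#' @param support_mask logical matrix neurons x electrodes; defaults to all
#'   TRUE.
#' @param derivatives optional list with arrays `d_time`, `d_amp`,
#'   `d_width` of the same shape as `templates`.
#' @return an object of class `bp_waveforms`.
#' @export
waveform_set <- function(templates, alignment_tap = NULL,
                         support_mask = NULL, derivatives = NULL) {
  stopifnot(is.array(templates), length(dim(templates)) == 3)
  d <- dim(templates)
  if (is.null(support_mask))
    support_mask <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(support_mask), d[1:2]))
  if (is.null(alignment_tap)) alignment_tap <- find_alignment_tap(templates)
  stopifnot(alignment_tap >= 1, alignment_tap <= d[3])
  structure(list(templates = templates,
                 n_neurons = d[1], n_electrodes = d[2], taps = d[3],
                 alignment_tap = as.integer(alignment_tap),
                 support_mask = support_mask,
                 derivatives = derivatives),
            class = "bp_waveforms")
}

# Tap of the negative extremum on the largest-norm electrode of the
# largest-norm neuron: the canonical alignment convention.
find_alignment_tap <- function(templates) {
  d <- dim(templates)
  norms <- apply(templates, c(1, 2), function(w) sum(w^2))
  idx <- which(norms == max(norms), arr.ind = TRUE)[1, ]
  w <- templates[idx[1], idx[2], ]
  as.integer(which.min(w))
}

#' @export
print.bp_waveforms <- function(x, ...) {
  cat(sprintf(paste0("<bp_waveforms> %d neurons x %d electrodes x %d taps",
                     " (alignment tap %d, %d/%d electrodes in support)\n"),
              x$n_neurons, x$n_electrodes, x$taps, x$alignment_tap,
              sum(x$support_mask), length(x$support_mask)))
  invisible(x)
}

# template of one neuron as an electrodes x taps matrix
neuron_template <- function(wf, j) {
  matrix(wf$templates[j, , ], wf$n_electrodes, wf$taps)
}

#' Peak-referenced spike times in seconds
#'
#' Spike bins mark where waveform tap 1 is placed, a convention that
#' differs between waveform sets (e.g. ground truth vs a sorter's
#' re-estimated templates). For comparisons across conventions, times are
#' referenced to each neuron's waveform trough:
#' (bin + peak_tap - 1 + subbin_offset) / rate, where peak_tap is the tap
#' of the negative extremum on that neuron's largest-norm electrode.
#'
#' @param spikes a [spike_events()] set.
#' @param waveforms the [waveform_set()] the spikes index into.
#' @param neuron_id optional neuron filter.
#' @return numeric vector of trough times in seconds, sorted.
#' @export
aligned_spike_times <- function(spikes, waveforms, neuron_id = NULL) {
  ev <- spikes$events
  if (!is.null(neuron_id)) ev <- ev[ev$neuron_id %in% neuron_id, ]
  if (is.na(spikes$sampling_rate_hz))
    stop("spike set has no sampling rate; cannot convert bins to seconds")
  peaks <- vapply(seq_len(waveforms$n_neurons), function(j) {
    w <- neuron_template(waveforms, j)
    e <- which.max(rowSums(w^2))
    which.min(w[e, ])
  }, 0L)
  sort((ev$bin + peaks[ev$neuron_id] - 1 + ev$subbin_offset) /
         spikes$sampling_rate_hz)
}

#' Squared norms of whitened templates, per neuron
#'
#' @param wf a `bp_waveforms` object.
#' @return numeric vector of sum-of-squares per neuron.
#' @export
template_norms <- function(wf) {
  apply(wf$templates, 1, function(w) sum(w^2))
}
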