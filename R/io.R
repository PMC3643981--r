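# File formats: flat little-endian float32 voltage + JSON sidecar, TSV
# event tables, plain-text waveform tensors with a shape header, JSON
# noise models and run manifests.

#' Write a recording to flat binary + JSON sidecar
#'
#' Voltage is stored electrode-major (all samples of electrode 1, then
#' electrode 2, ...) as little-endian 32-bit floats; the sidecar records
#' n_electrodes, sampling_rate_hz, n_samples, dtype, layout and geometry.
#'
#' @param recording a [new_recording()].
#' @param path data file path (e.g. `rec.f32`).
#' @param header_path sidecar path (default `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            header_path = paste0(path, ".json")) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = 4, endian = "little")
  hdr <- list(n_electrodes = recording$n_electrodes,
              sampling_rate_hz = recording$sampling_rate_hz,
              n_samples = recording$n_samples,
              dtype = "float32", layout = "electrode_major",
              geometry = recording$geometry)
  jsonlite::write_json(hdr, header_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path data file path.
#' @param header_path sidecar path.
#' @return a [new_recording()].
#' @export
read_recording <- function(path, header_path = paste0(path, ".json")) {
  hdr <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  if (!identical(hdr$dtype, "float32"))
    stop("unknown dtype: ", hdr$dtype)
  expected <- hdr$n_electrodes * hdr$n_samples * 4
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf("size mismatch: expected %d bytes, found %s bytes",
                 expected, format(actual)))
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = hdr$n_electrodes * hdr$n_samples,
               size = 4, endian = "little")
  V <- t(matrix(x, hdr$n_samples, hdr$n_electrodes))
  new_recording(V, hdr$sampling_rate_hz, as.data.frame(hdr$geometry))
}

#' Write a spike event set to TSV
#'
#' Columns: neuron_id, bin (0-based), subbin_offset, amp_coef,
#' width_coef. Header row mandatory. Metadata (n_bins, n_neurons,
#' sampling rate) goes into `#`-prefixed comment lines.
#'
#' @param spikes a [spike_events()] set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_bins=%d n_neurons=%d sampling_rate_hz=%s",
                     spikes$n_bins, spikes$n_neurons,
                     format(spikes$sampling_rate_hz, digits = 17)), con)
  utils::write.table(format(spikes$events, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike event set written by [write_spikes()]
#'
#' @param path TSV path.
#' @param n_bins,n_neurons,sampling_rate_hz overrides; defaults come from
#'   the comment header.
#' @return a [spike_events()] set.
#' @export
read_spikes <- function(path, n_bins = NULL, n_neurons = NULL,
                        sampling_rate_hz = NULL) {
  first <- readLines(path, n = 1)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[-0-9.eE+NAInf]+", first))[[1]]
    for (s in kv) {
      p <- strsplit(s, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- as.numeric(p[2])
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  need <- c("neuron_id", "bin", "subbin_offset", "amp_coef", "width_coef")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  spike_events(df,
               n_bins = n_bins %||% meta$n_bins,
               n_neurons = n_neurons %||% meta$n_neurons,
               sampling_rate_hz = sampling_rate_hz %||%
                 (meta$sampling_rate_hz %||% NA_real_))
}

#' Write a waveform tensor to a plain-text file with a shape header
#'
#' @param waveforms a [waveform_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(waveforms, path) {
  obj <- list(shape = dim(waveforms$templates),
              alignment_tap = waveforms$alignment_tap,
              support_mask = waveforms$support_mask,
              templates = as.numeric(waveforms$templates))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read a waveform tensor written by [write_waveforms()]
#'
#' @param path file path.
#' @return a [waveform_set()].
#' @export
read_waveforms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tmpl <- array(obj$templates, obj$shape)
  waveform_set(tmpl, alignment_tap = obj$alignment_tap,
               support_mask = matrix(obj$support_mask,
                                     obj$shape[1], obj$shape[2]))
}

#' Write a fitted noise model (covariances and whitening filters) to JSON
#'
#' @param noise_model a `bp_noise_model` from [whiten_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_noise_model <- function(noise_model, path) {
  nm <- noise_model
  obj <- list(window_bins = nm$window_bins, center = nm$center,
              temporal_filter = as.numeric(nm$temporal_filter),
              n_electrodes = ncol(nm$temporal_filter),
              temporal_cov_first_row = lapply(nm$temporal_cov,
                                              function(C) C[1, ]),
              spatial_cov = as.numeric(nm$spatial_cov),
              spatial_whitener = as.numeric(nm$spatial_whitener))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a noise model written by [write_noise_model()]
#'
#' @param path file path.
#' @return a `bp_noise_model`.
#' @export
read_noise_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  E <- obj$n_electrodes
  fr <- obj$temporal_cov_first_row
  if (is.matrix(fr)) fr <- lapply(seq_len(nrow(fr)), function(i) fr[i, ])
  structure(list(
    temporal_cov = lapply(seq_len(E), function(e) toeplitz_sym(fr[[e]])),
    temporal_filter = matrix(obj$temporal_filter, obj$window_bins, E),
    center = obj$center, window_bins = obj$window_bins,
    spatial_cov = matrix(obj$spatial_cov, E, E),
    spatial_whitener = matrix(obj$spatial_whitener, E, E)),
    class = "bp_noise_model")
}

#' Write a cross-correlogram to TSV
#'
#' @param ccf a `bp_ccf` from [cross_correlogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ccf <- function(ccf, path) {
  df <- data.frame(lag_ms = ccf$lags_ms, rate_hz = ccf$rate_hz,
                   count = ccf$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline: simulate, initialize, sort, diagnose
#'
#' Executes the stages end to end and writes every artifact plus a JSON
#' manifest (config, seeds, counts, error rate when ground truth exists)
#' so a run is exactly repeatable.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; all stage seeds derive from it.
#' @param sim_args arguments passed to [simulate_recording()] (set to
#'   NULL and supply `recording` to sort existing data).
#' @param recording optional existing [new_recording()].
#' @param init_spikes optional initial spike estimate; defaults to
#'   running [cluster_init()].
#' @param k neuron count for the initializer (NULL: silhouette).
#' @param config a [bp_config()].
#' @return the manifest list, invisibly; artifacts land in `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1, sim_args = list(),
                         recording = NULL, init_spikes = NULL, k = NULL,
                         config = bp_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config = unclass(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  truth <- NULL
  if (is.null(recording)) {
    if (is.null(sim_args)) stop("no recording supplied and simulation disabled")
    sim <- do.call(simulate_recording, c(sim_args, list(seed = seed)))
    recording <- sim$recording
    truth <- sim$spikes
    write_spikes(truth, file.path(out_dir, "truth_spikes.tsv"))
    manifest$simulated <- TRUE
  }
  write_recording(recording, file.path(out_dir, "recording.f32"))
  if (is.null(init_spikes)) {
    init <- cluster_init(recording, config, k = k, seed = seed + 1)
    init_spikes <- init$spikes
    manifest$init <- list(k = init$k, n_spikes = nrow(init_spikes$events),
                          silhouette = init$silhouette)
  }
  write_spikes(init_spikes, file.path(out_dir, "init_spikes.tsv"))
  fit <- coordinate_ascent(recording, init_spikes, config)
  write_spikes(fit$spikes, file.path(out_dir, "sorted_spikes.tsv"))
  write_waveforms(fit$waveforms_w, file.path(out_dir, "waveforms_w.json"))
  write_noise_model(fit$noise_model, file.path(out_dir, "noise_model.json"))
  manifest$n_sorted <- nrow(fit$spikes$events)
  manifest$objective <- utils::tail(fit$objective_trace, 1)
  dur <- recording$n_samples / recording$sampling_rate_hz
  manifest$contamination_pct <- vapply(seq_len(fit$spikes$n_neurons),
    function(j) contamination_rate(fit$spikes, config$refractory_ms, dur,
                                   neuron_id = j), 0)
  if (!is.null(truth)) {
    errs <- vapply(seq_len(truth$n_neurons), function(j) {
      m <- match_spikes(spike_times(fit$spikes, j), spike_times(truth, j),
                        tol = 0.5e-3)
      c(m$misses + m$false_positives, length(spike_times(truth, j)))
    }, numeric(2))
    manifest$error_rate_pct <- 100 * sum(errs[1, ]) / sum(errs[2, ])
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
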