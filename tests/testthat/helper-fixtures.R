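# Shared fixture builders and small independent oracles.

# tiny two-neuron geometry with well-separated templates
tiny_waveforms <- function(n_electrodes = 4, taps = 30, amps = c(8, 8),
                           lambda = 1.2) {
  geom <- electrode_grid(n_electrodes)
  J <- length(amps)
  tmpl <- array(0, c(J, n_electrodes, taps))
  for (j in seq_len(J)) {
    pos <- c(geom$x[j], geom$y[j])
    tmpl[j, , ] <- make_waveform(geom, pos, amps[j], lambda = lambda,
                                 taps = taps,
                                 trough_peak_ratio = 0.3 + 0.1 * j)
  }
  list(wf = waveform_set(tmpl), geom = geom)
}

# deterministic spike set from explicit (neuron, bin) pairs
spikes_at <- function(neuron_id, bin, n_bins, n_neurons,
                      rate = 20000, subbin = NULL) {
  df <- data.frame(neuron_id = neuron_id, bin = bin)
  if (!is.null(subbin)) df$subbin_offset <- subbin
  spike_events(df, n_bins = n_bins, n_neurons = n_neurons,
               sampling_rate_hz = rate)
}

# all permutations of 1..n (n small), for label-agreement oracles
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force maximum one-to-one matching within tolerance (bipartite
# assignment by recursion; oracle for match_spikes on tiny instances)
brute_force_hits <- function(est, tru, tol) {
  est <- sort(est); tru <- sort(tru)
  feas <- lapply(seq_along(est), function(i)
    which(abs(tru - est[i]) <= tol))
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(est)) return(0L)
    top <- recurse(i + 1L, used)  # skip est[i]
    for (k in setdiff(feas[[i]], used)) {
      top <- max(top, 1L + recurse(i + 1L, c(used, k)))
    }
    top
  }
  if (length(est) == 0 || length(tru) == 0) return(0L)
  recurse(1L, integer())
}

# greedy label matching between estimated and true neurons based on
# spike-time hits; returns permutation perm[true] = estimated
match_neurons <- function(est_times, true_times, tol = 0.5e-3) {
  J <- length(true_times)
  H <- matrix(0, J, J)
  for (j in seq_len(J)) for (k in seq_len(J))
    H[j, k] <- match_spikes(est_times[[k]], true_times[[j]], tol)$hits
  perm <- integer(J); used <- logical(J)
  for (r in order(-apply(H, 1, max))) {
    k <- which.max(ifelse(used, -1, H[r, ]))
    perm[r] <- k
    used[k] <- TRUE
  }
  perm
}

# total error rate (%) of a fit against simulator ground truth, matching
# neurons up to permutation and referencing times to waveform troughs
fit_error_rate <- function(fit, sim, tol = 0.5e-3) {
  J <- sim$spikes$n_neurons
  ft <- lapply(seq_len(J), function(k)
    aligned_spike_times(fit$spikes, fit$waveforms_w, k))
  tt <- lapply(seq_len(J), function(j)
    aligned_spike_times(sim$spikes, sim$waveforms, j))
  perm <- match_neurons(ft, tt, tol)
  err <- 0; tru <- 0
  for (j in seq_len(J)) {
    m <- match_spikes(ft[[perm[j]]], tt[[j]], tol)
    err <- err + m$misses + m$false_positives
    tru <- tru + length(tt[[j]])
  }
  100 * err / tru
}
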