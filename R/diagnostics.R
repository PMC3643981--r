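# Ground-truth-free and ground-truth-based quality metrics:
# cross-correlograms and the zero-lag notch artifact index (a proxy for
# missed near-synchronous spikes), refractory contamination rate (a proxy
# for false positives), spike matching, prior-sensitivity analysis and the
# power-law calibration of sensitivity against true error rate.

#' Cross-correlogram of two spike trains
#'
#' Conditional firing rate of train b as a function of lag relative to
#' each spike of train a: a histogram of (t_b - t_a) over all pairs within
#' the window, divided by n_ref x bin duration.
#'
#' @param train_a,train_b spike times in seconds (or [spike_events()]
#'   sets with a sampling rate, filtered with `neuron_a` / `neuron_b`).
#' @param window_ms half-width of the lag window (multiple of `bin_ms`).
#' @param bin_ms lag bin width.
#' @param duration_s recording duration (for the baseline rate).
#' @return object of class `bp_ccf`: `lags_ms` (bin centers), `rate_hz`,
#'   `baseline_hz`, `n_ref`, `counts`.
#' @export
cross_correlogram <- function(train_a, train_b, window_ms = 10,
                              bin_ms = 0.5, duration_s) {
  a <- sort(as.numeric(train_a))
  b <- sort(as.numeric(train_b))
  nb <- round(window_ms / bin_ms)
  if (abs(nb - window_ms / bin_ms) > 1e-9)
    stop("window_ms must be a multiple of bin_ms")
  breaks <- seq(-nb, nb) * bin_ms / 1000
  centers <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2 * 1000
  counts <- numeric(length(centers))
  w <- window_ms / 1000
  if (length(a) && length(b)) {
    lo <- findInterval(a - w, b) + 1L
    hi <- findInterval(a + w, b)
    for (i in seq_along(a)) {
      if (hi[i] < lo[i]) next
      d <- b[lo[i]:hi[i]] - a[i]
      h <- findInterval(d, breaks, rightmost.closed = TRUE)
      h <- h[h >= 1 & h <= length(counts)]
      counts <- counts + tabulate(h, length(counts))
    }
  }
  rate <- if (length(a)) counts / (length(a) * bin_ms / 1000) else counts
  structure(list(lags_ms = centers, rate_hz = rate,
                 baseline_hz = length(b) / duration_s,
                 n_ref = length(a), counts = counts, bin_ms = bin_ms),
            class = "bp_ccf")
}

#' @export
print.bp_ccf <- function(x, ...) {
  cat(sprintf("<bp_ccf> %d lags (+-%g ms), %d reference spikes, baseline %.2f Hz\n",
              length(x$lags_ms), max(abs(x$lags_ms)) + x$bin_ms / 2,
              x$n_ref, x$baseline_hz))
  invisible(x)
}

#' Zero-lag notch artifact index of a cross-correlogram
#'
#' (mean rate over notch < |lag| <= flank) minus (mean rate over
#' |lag| <= notch), divided by the baseline rate. Positive values flag
#' the spurious central notch produced when a sorter misses
#' near-synchronous spikes; scale-invariant by construction.
#'
#' @param ccf a `bp_ccf`.
#' @param notch_ms half-width of the central notch window (default 1 ms).
#' @param flank_ms outer edge of the flank window (default 5 ms).
#' @return scalar index (NA when the baseline is zero).
#' @export
ccf_artifact_index <- function(ccf, notch_ms = 1, flank_ms = 5) {
  stopifnot(flank_ms > notch_ms)
  if (ccf$baseline_hz <= 0) return(NA_real_)
  al <- abs(ccf$lags_ms)
  notch <- al <= notch_ms
  flank <- al > notch_ms & al <= flank_ms
  (mean(ccf$rate_hz[flank]) - mean(ccf$rate_hz[notch])) / ccf$baseline_hz
}

#' Refractory-period contamination rate
#'
#' Ratio of the rate of spikes occurring inside another spike's refractory
#' window to the rate of spikes outside those windows, as a percentage,
#' with time-occupancy correction: in-window spikes are counted against
#' the union length of all refractory windows, out-of-window spikes
#' against the remaining time. 100% means refractory violations occur at
#' the baseline rate (e.g. a Poisson train); 0% means none.
#'
#' @param times spike times in seconds (sorted or not), or a
#'   [spike_events()] set plus `neuron_id`.
#' @param refractory_ms refractory window after each spike, ms.
#' @param duration_s total recording duration.
#' @param neuron_id neuron filter when `times` is a spike set.
#' @return contamination rate in percent (NA for < 2 spikes).
#' @export
contamination_rate <- function(times, refractory_ms = 1.5, duration_s,
                               neuron_id = NULL) {
  if (inherits(times, "bp_spikes")) times <- spike_times(times, neuron_id)
  t <- sort(as.numeric(times))
  if (length(t) < 2) return(NA_real_)
  stopifnot(refractory_ms > 0, duration_s > 0)
  r <- refractory_ms / 1000
  isi <- diff(t)
  in_window <- c(FALSE, isi < r)
  n_in <- sum(in_window)
  n_out <- length(t) - n_in
  # occupancy: union of (t_i, t_i + r], clipped to the recording
  starts <- t
  ends <- pmin(t + r, duration_s)
  merged_in <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      merged_in <- merged_in + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  t_in <- merged_in + (cur_e - cur_s)
  t_out <- duration_s - t_in
  if (t_in <= 0 || t_out <= 0 || n_out == 0) return(NA_real_)
  100 * (n_in / t_in) / (n_out / t_out)
}

#' Match estimated spikes to ground truth
#'
#' One-to-one matching maximizing the number of hits within the
#' tolerance (optimal for interval matching on a line: both trains
#' sorted, earliest-feasible pairing).
#'
#' @param estimated,truth spike times (seconds) or bin indices; use one
#'   unit consistently.
#' @param tol matching tolerance, same unit.
#' @return list: `hits`, `misses`, `false_positives`, `error_rate`
#'   (misses + false positives over true count, in percent), and the
#'   matched index pairs.
#' @export
match_spikes <- function(estimated, truth, tol) {
  stopifnot(tol >= 0)
  est <- sort(as.numeric(estimated))
  tru <- sort(as.numeric(truth))
  i <- 1L; k <- 1L
  pairs <- list()
  while (i <= length(est) && k <= length(tru)) {
    d <- est[i] - tru[k]
    if (abs(d) <= tol) {
      pairs[[length(pairs) + 1L]] <- c(i, k)
      i <- i + 1L; k <- k + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      k <- k + 1L
    }
  }
  hits <- length(pairs)
  misses <- length(tru) - hits
  fp <- length(est) - hits
  list(hits = hits, misses = misses, false_positives = fp,
       error_rate = if (length(tru))
         100 * (misses + fp) / length(tru) else NA_real_,
       pairs = if (hits) do.call(rbind, pairs) else
         matrix(integer(), 0, 2))
}

#' Sensitivity of spike count to the prior multiplier
#'
#' Re-runs spike estimation over a grid of penalty multipliers for one
#' neuron and measures |d log(count) / d log(multiplier)| at the default
#' multiplier by a central log-log finite difference over the grid
#' neighbors. A well-isolated unit has sensitivity near zero.
#'
#' @param count_fn function(multiplier) returning the spike count of the
#'   neuron under that penalty multiplier (see [resolve_spikes()]).
#' @param multipliers penalty multipliers, spanning at least an order of
#'   magnitude around `default`.
#' @param default the default multiplier at which the derivative is taken
#'   (must be in `multipliers`).
#' @param count_floor counts are floored at this value before taking logs
#'   (half-count quantization guard).
#' @return object of class `bp_sensitivity`: `multipliers`, `counts`,
#'   `sensitivity`.
#' @export
sensitivity_analysis <- function(count_fn, multipliers, default,
                                 count_floor = 0.5) {
  multipliers <- sort(multipliers)
  stopifnot(length(multipliers) >= 3, default %in% multipliers)
  counts <- vapply(multipliers, count_fn, 0)
  i <- match(default, multipliers)
  lo <- max(i - 1L, 1L); hi <- min(i + 1L, length(multipliers))
  c_lo <- max(counts[lo], count_floor)
  c_hi <- max(counts[hi], count_floor)
  if (counts[i] == 0)
    warning("zero spike count at the default multiplier; sensitivity unreliable")
  sens <- abs((log(c_hi) - log(c_lo)) /
              (log(multipliers[hi]) - log(multipliers[lo])))
  structure(list(multipliers = multipliers, counts = counts,
                 sensitivity = sens, default = default),
            class = "bp_sensitivity")
}

#' @export
print.bp_sensitivity <- function(x, ...) {
  cat(sprintf("<bp_sensitivity> counts %s over multipliers %s; sensitivity %.3f\n",
              paste(x$counts, collapse = "/"),
              paste(signif(x$multipliers, 3), collapse = "/"),
              x$sensitivity))
  invisible(x)
}

#' Power-law calibration of error rate against prior sensitivity
#'
#' Ordinary least squares of log(error rate) on log(sensitivity); the
#' predictor maps a sensitivity measured on real data (no ground truth)
#' to an expected error rate.
#'
#' @param sensitivities,error_rates positive vectors (>= 3 points).
#' @return list: `exponent`, `prefactor`, `r_squared`, and `predict`, a
#'   function(sensitivity) -> error rate.
#' @export
fit_powerlaw <- function(sensitivities, error_rates) {
  stopifnot(length(sensitivities) == length(error_rates))
  if (length(sensitivities) < 3) stop("need at least 3 points")
  if (any(sensitivities <= 0) || any(error_rates <= 0))
    stop("all inputs must be > 0 (floor zeros before fitting)")
  fit <- stats::lm(log(error_rates) ~ log(sensitivities))
  co <- stats::coef(fit)
  exponent <- unname(co[2]); prefactor <- unname(exp(co[1]))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  list(exponent = exponent, prefactor = prefactor,
       r_squared = r2,
       predict = function(s) prefactor * s^exponent)
}

#' Scalar signal-detection simulation
#'
#' Monte-Carlo detection of a scalar signal (mean `snr`, sd 1, prior
#' probability `prior_p`) against pure noise (mean 0, sd 1) over a grid
#' of thresholds: the low-dimensional caricature of per-spike detection,
#' whose detection-count stability over thresholds mirrors the prior
#' sensitivity of a well-isolated unit. The error-minimizing threshold
#' has the closed form snr/2 + log((1-p)/p)/snr.
#'
#' @param snr signal mean over noise sd.
#' @param prior_p signal prior probability.
#' @param thresholds numeric threshold grid.
#' @param n_trials Monte-Carlo trials (>= 1e4 for the stated tolerances).
#' @param seed RNG seed.
#' @return data.frame: `threshold`, `detections` (fraction of trials
#'   above threshold), `errors` (miss + false-positive fraction).
#' @export
scalar_detection_sim <- function(snr, prior_p, thresholds, n_trials = 1e4,
                                 seed = 1) {
  stopifnot(snr > 0, prior_p > 0, prior_p < 1)
  with_seed(seed, {
    s <- stats::runif(n_trials) < prior_p
    x <- stats::rnorm(n_trials, mean = ifelse(s, snr, 0))
    det <- vapply(thresholds, function(th) mean(x > th), 0)
    err <- vapply(thresholds, function(th)
      mean((s & x <= th) | (!s & x > th)), 0)
    data.frame(threshold = thresholds, detections = det, errors = err)
  })
}
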