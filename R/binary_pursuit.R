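# Greedy MAP spike estimation ("binary pursuit"). Works in the whitened
# space, where the negative log posterior is
#   L(X) = 1/2 ||V - W*X||^2 + sum_j theta_j n_j ,
# and the gain of inserting a spike of neuron j at bin t is
#   dL = w_j . r[footprint] - 1/2 ||w_j||^2 - theta_j .
# The solver flips the globally best (neuron, bin) until no insertion or
# deletion improves the objective, updating the residual and the gain
# surface only over the affected spatiotemporal footprint.

#' Solver configuration
#'
#' @param taps waveform length in bins (default 30; ~1.5 ms at 20 kHz).
#' @param threshold_multiplier detection threshold for the clustering
#'   initializer, in robust noise SDs.
#' @param n_dims principal components kept by the initializer.
#' @param prune_a pruning constant (waveform norm vs electrode noise SD).
#' @param window_bins temporal noise-covariance window (16 bins = 0.8 ms
#'   at 20 kHz).
#' @param prior_multiplier multiplicative factor on the plug-in per-spike
#'   penalty theta_j = log((1-p_j)/p_j); default 6, the factor at which
#'   the miss/false-positive trade-off balances.
#' @param correct derivative terms enabled for the per-spike Taylor
#'   variability correction: any of `"time"`, `"amp"`, `"width"`.
#'   Default time only. `character(0)` disables the correction.
#' @param gamma ridge penalty of the correction; NULL for the default
#'   0.1 * trace(D'D) / ncol(D), per neuron.
#' @param clamp bound on each correction coefficient.
#' @param block_s block length for block processing, seconds.
#' @param rounds coordinate-ascent rounds (default 1).
#' @param tol_frac termination tolerance as a fraction of the largest
#'   squared template norm.
#' @param max_iter per-block iteration cap (warning when reached).
#' @param refractory_ms refractory window used by diagnostics (the solver
#'   itself does not enforce refractoriness, faithful to the model).
#' @return a list of class `bp_config`.
#' @export
bp_config <- function(taps = 30, threshold_multiplier = 4, n_dims = 5,
                      prune_a = 1, window_bins = 16, prior_multiplier = 6,
                      correct = "time", gamma = NULL, clamp = 0.5,
                      block_s = 1, rounds = 1, tol_frac = 1e-9,
                      max_iter = 20000, refractory_ms = 1.5) {
  stopifnot(taps >= 4, threshold_multiplier > 0, prune_a >= 0,
            prior_multiplier > 0, clamp > 0, block_s > 0, rounds >= 1,
            tol_frac >= 0, all(correct %in% c("time", "amp", "width")))
  structure(as.list(environment()), class = "bp_config")
}

#' Per-spike penalty weights from Bernoulli prior probabilities
#'
#' theta_j = multiplier * log((1 - p_j) / p_j), the log prior odds against
#' a spike in any one bin, optionally scaled by a multiplicative factor.
#'
#' @param p per-neuron per-bin spike probability, 0 < p < 0.5.
#' @param multiplier scalar factor on the plug-in penalty.
#' @return numeric vector theta.
#' @export
compute_prior_weights <- function(p, multiplier = 1) {
  if (any(p <= 0 | p > 0.5)) stop("p must lie in (0, 0.5]")
  multiplier * log((1 - p) / p)
}

#' Change in log posterior for inserting one spike
#'
#' dL = w . r[segment] - ||w||^2 / 2 - theta, using only the samples in
#' the template's footprint (unit noise variance after whitening).
#'
#' @param residual whitened electrodes x samples residual matrix (the
#'   candidate spike not included).
#' @param whitened_template electrodes x taps template.
#' @param theta per-spike penalty for this neuron.
#' @param bin 0-based bin at which waveform tap 1 would be placed.
#' @return the scalar gain.
#' @export
delta_loglik <- function(residual, whitened_template, theta, bin) {
  L <- ncol(whitened_template)
  if (bin < 0 || bin + L > ncol(residual))
    stop("template footprint extends past the segment")
  seg <- residual[, (bin + 1):(bin + L), drop = FALSE]
  sum(whitened_template * seg) - sum(whitened_template^2) / 2 - theta
}

#' Ridge-regularized Taylor variability correction
#'
#' Solves coefs = (D'D + gamma I)^-1 D' r for the sub-bin time shift,
#' amplitude and width coefficients of one spike, clamps them, and
#' subtracts D coefs from the residual segment. If the (clamped)
#' correction would increase the residual norm it is dropped.
#'
#' @param residual_segment electrodes x taps residual with the canonical
#'   template already subtracted.
#' @param D derivative design matrix, (electrodes*taps) x k.
#' @param gamma ridge penalty (>= 0).
#' @param clamp coefficient bound.
#' @param P optional precomputed projection (D'D + gamma I)^-1 D'.
#' @return list with `coefs` (length k) and `corrected` segment.
#' @export
apply_variability_correction <- function(residual_segment, D, gamma = 0,
                                         clamp = 0.5, P = NULL) {
  if (gamma < 0) stop("gamma must be >= 0")
  r <- as.numeric(residual_segment)
  if (is.null(P)) P <- correction_projector(D, gamma)
  coefs <- pmin(pmax(as.numeric(P %*% r), -clamp), clamp)
  corr <- r - as.numeric(D %*% coefs)
  if (sum(corr^2) > sum(r^2)) {  # clamped step not a descent step
    coefs[] <- 0
    corr <- r
  }
  list(coefs = coefs,
       corrected = matrix(corr, nrow(residual_segment)))
}

# (D'D + gamma I)^-1 D', precomputed once per neuron
correction_projector <- function(D, gamma) {
  DtD <- crossprod(D)
  if (gamma == 0 && rcond(DtD) < 1e-12)
    stop("singular D'D with gamma = 0; use gamma > 0")
  solve(DtD + diag(gamma, ncol(D)), t(D))
}

# Derivative designs and projectors for all neurons.
build_correctors <- function(wf, config) {
  if (!length(config$correct)) return(NULL)
  if (is.null(wf$derivatives))
    stop("waveforms carry no derivative tensors; run compute_derivatives()")
  key <- c(time = "d_time", amp = "d_amp", width = "d_width")[config$correct]
  lapply(seq_len(wf$n_neurons), function(j) {
    D <- vapply(key, function(nm) as.numeric(wf$derivatives[[nm]][j, , ]),
                numeric(wf$n_electrodes * wf$taps))
    D <- matrix(D, ncol = length(key))
    gamma <- config$gamma %||% (0.1 * sum(diag(crossprod(D))) / ncol(D))
    list(D = D, gamma = gamma,
         P = correction_projector(D, gamma), terms = config$correct)
  })
}

# b[t, j] = w_j . r[footprint at bin t] for all valid t (1-based), via a
# per-electrode delay embedding and one BLAS product per electrode.
correlate_templates <- function(r, Wrev) {
  L <- nrow(Wrev[[1]])
  Tval <- ncol(r) - L + 1
  b <- matrix(0, Tval, ncol(Wrev[[1]]))
  for (e in seq_along(Wrev)) {
    if (all(Wrev[[e]] == 0)) next
    b <- b + stats::embed(r[e, ], L) %*% Wrev[[e]]
  }
  b
}

#' Greedy binary pursuit on one (whitened) segment
#'
#' Starts from the all-zero spike lattice, repeatedly flips the (neuron,
#' bin) with the globally largest positive gain (ties: lowest neuron id,
#' then lowest bin), updating the residual and gains only over the
#' affected footprint, until no single insertion or deletion improves the
#' objective by more than the tolerance. Immediately after each insertion
#' the Taylor variability correction is applied (if enabled) and the
#' exact subtracted waveform is remembered so a later deletion restores
#' it bit-exactly.
#'
#' @param V whitened voltage, a [new_recording()] or electrodes x samples
#'   matrix.
#' @param waveforms whitened [waveform_set()] (with derivatives if the
#'   correction is enabled).
#' @param theta per-neuron penalty vector.
#' @param config a [bp_config()].
#' @param bin_offset added to reported bins (used by block processing).
#' @return a [spike_events()] set with attributes `residual`, `objective`
#'   (final value), `objective_trace` and `flips` (when
#'   `config$track = TRUE`).
#' @export
greedy_solve <- function(V, waveforms, theta, config = bp_config(),
                         bin_offset = 0L) {
  Vm <- if (inherits(V, "bp_recording")) V$data else V
  if (any(!is.finite(Vm))) stop("non-finite voltage")
  wf <- waveforms
  E <- wf$n_electrodes; L <- wf$taps; J <- wf$n_neurons
  T_ <- ncol(Vm)
  stopifnot(nrow(Vm) == E, length(theta) == J, T_ >= L)
  Tval <- T_ - L + 1L
  Wseg <- lapply(seq_len(J), function(j) neuron_template(wf, j))
  Wrev <- lapply(seq_len(E), function(e) {
    m <- vapply(Wseg, function(w) rev(w[e, ]), numeric(L))
    matrix(m, L, J)
  })
  n2 <- vapply(Wseg, function(w) sum(w^2), 0)
  tol <- config$tol_frac * max(n2, 1e-300)
  correctors <- build_correctors(wf, config)
  r <- Vm
  b <- correlate_templates(r, Wrev)
  G <- sweep(b, 2, n2 / 2 + theta)         # insertion gains, X = 0
  occ <- matrix(0L, Tval, J)
  events <- list()
  segs <- list()
  obj <- sum(r^2) / 2
  trace <- if (isTRUE(config$track)) obj else NULL
  flips <- if (isTRUE(config$track)) list() else NULL
  iter <- 0L
  repeat {
    i <- which.max(G)
    g <- G[i]
    if (!is.finite(g) || g <= tol) break
    iter <- iter + 1L
    if (iter > config$max_iter) {
      warning("iteration cap reached; returning partial solution")
      break
    }
    t0 <- ((i - 1L) %% Tval) + 1L
    j <- ((i - 1L) %/% Tval) + 1L
    cols <- t0:(t0 + L - 1L)
    seg_before <- sum(r[, cols]^2)
    if (occ[t0, j] == 0L) {                     # insert
      sub <- Wseg[[j]]
      coefs <- numeric(3)
      if (!is.null(correctors) && n2[j] > 0) {
        cr <- correctors[[j]]
        fx <- apply_variability_correction(r[, cols, drop = FALSE] - sub,
                                           cr$D, cr$gamma, config$clamp,
                                           P = cr$P)
        extra <- matrix(as.numeric(cr$D %*% fx$coefs), E, L)
        sub <- sub + extra
        coefs[match(cr$terms, c("time", "amp", "width"))] <- fx$coefs
      }
      r[, cols] <- r[, cols] - sub
      id <- length(events) + 1L
      events[[id]] <- list(j = j, t = t0, coefs = coefs)
      segs[[id]] <- sub
      occ[t0, j] <- id
      obj_delta <- (sum(r[, cols]^2) - seg_before) / 2 + theta[j]
      action <- "insert"
    } else {                                    # delete: restore exactly
      id <- occ[t0, j]
      r[, cols] <- r[, cols] + segs[[id]]
      events[id] <- list(NULL)
      segs[id] <- list(NULL)
      occ[t0, j] <- 0L
      obj_delta <- (sum(r[, cols]^2) - seg_before) / 2 - theta[j]
      action <- "delete"
    }
    obj <- obj + obj_delta
    # refresh b and gains over every bin whose footprint was touched
    lo <- max(1L, t0 - L + 1L)
    hi <- min(Tval, t0 + L - 1L)
    rcols <- lo:min(T_, hi + L - 1L)
    bloc <- matrix(0, hi - lo + 1L, J)
    for (e in seq_len(E)) {
      if (all(Wrev[[e]] == 0)) next
      bloc <- bloc + stats::embed(r[e, rcols], L) %*% Wrev[[e]]
    }
    b[lo:hi, ] <- bloc
    G[lo:hi, ] <- sweep(bloc, 2, n2 / 2 + theta)
    occ_loc <- which(occ[lo:hi, , drop = FALSE] != 0L, arr.ind = TRUE)
    for (k in seq_len(nrow(occ_loc))) {
      tt <- lo + occ_loc[k, 1] - 1L
      jj <- occ_loc[k, 2]
      s <- segs[[occ[tt, jj]]]
      G[tt, jj] <- -sum(s * r[, tt:(tt + L - 1L)]) - sum(s^2) / 2 + theta[jj]
    }
    if (isTRUE(config$track)) {
      trace <- c(trace, obj)
      flips[[length(flips) + 1L]] <-
        data.frame(action = action, neuron_id = j, bin = t0 - 1L + bin_offset,
                   gain = g)
    }
  }
  keep <- !vapply(events, is.null, TRUE)
  ev <- do.call(rbind, lapply(events[keep], function(x)
    data.frame(neuron_id = x$j, bin = x$t - 1L + bin_offset,
               subbin_offset = x$coefs[1], amp_coef = x$coefs[2],
               width_coef = x$coefs[3])))
  if (is.null(ev))
    ev <- data.frame(neuron_id = integer(), bin = integer())
  out <- spike_events(ev, n_bins = T_ + bin_offset, n_neurons = J,
                      sampling_rate_hz =
                        if (inherits(V, "bp_recording"))
                          V$sampling_rate_hz else NA_real_)
  attr(out, "residual") <- r
  attr(out, "objective") <- obj
  if (isTRUE(config$track)) {
    attr(out, "objective_trace") <- trace
    attr(out, "flips") <- do.call(rbind, flips)
  }
  out
}

#' Block processing wrapper for binary pursuit
#'
#' Splits the recording into `block_s`-second blocks. Each block is solved
#' on data padded by one template length on either side, but only events
#' whose bin lies in the block's own zone are reported, so a spike
#' straddling a boundary is recovered exactly once and results for
#' isolated spikes do not depend on the block size.
#'
#' @inheritParams greedy_solve
#' @param recording_w whitened [new_recording()].
#' @return a [spike_events()] set over the full recording.
#' @export
process_blocks <- function(recording_w, waveforms, theta,
                           config = bp_config()) {
  fs <- recording_w$sampling_rate_hz
  T_ <- recording_w$n_samples
  L <- waveforms$taps
  B <- as.integer(round(config$block_s * fs))
  if (B <= 2L * L) stop("block length must exceed twice the template span")
  starts <- seq(0L, max(T_ - 1L, 0L), by = B)   # 0-based zone starts
  all_ev <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    e <- min(s + B, T_)
    lo <- max(0L, s - L)
    hi <- min(T_, e + L)
    sub <- recording_w$data[, (lo + 1L):hi, drop = FALSE]
    if (ncol(sub) < L) next
    res <- greedy_solve(sub, waveforms, theta, config, bin_offset = lo)
    ev <- res$events
    all_ev[[k]] <- ev[ev$bin >= s & ev$bin < e, , drop = FALSE]
  }
  ev <- do.call(rbind, all_ev)
  spike_events(ev %||% data.frame(neuron_id = integer(), bin = integer()),
               n_bins = T_, n_neurons = waveforms$n_neurons,
               sampling_rate_hz = fs)
}

#' Negative log posterior of a spike configuration
#'
#' 1/2 ||V - prediction||^2 + sum_j theta_j n_j, evaluated from scratch in
#' the whitened space (the brute-force counterpart of the solver's
#' incremental bookkeeping).
#'
#' @param V whitened recording or matrix.
#' @param waveforms whitened [waveform_set()].
#' @param spikes a [spike_events()] set.
#' @param theta penalty vector.
#' @return scalar objective value.
#' @export
bp_objective <- function(V, waveforms, spikes, theta) {
  Vm <- if (inherits(V, "bp_recording")) V$data else V
  pred <- predict_voltage(waveforms, spikes, ncol(Vm))
  counts <- tabulate(spikes$events$neuron_id, spikes$n_neurons)
  sum((Vm - pred)^2) / 2 + sum(theta * counts)
}

#' Exhaustive single-flip scan of a solution
#'
#' Recomputes, from the residual, the gain of every possible single
#' insertion and every single deletion. At a local optimum of the greedy
#' solver no gain exceeds the termination tolerance.
#'
#' @inheritParams bp_objective
#' @return list with `max_gain`, and the full `insert_gains` matrix
#'   (bins x neurons) and `delete_gains` per event.
#' @export
scan_single_flips <- function(V, waveforms, spikes, theta) {
  Vm <- if (inherits(V, "bp_recording")) V$data else V
  wf <- waveforms
  L <- wf$taps; J <- wf$n_neurons; E <- wf$n_electrodes
  r <- Vm - predict_voltage(wf, spikes, ncol(Vm))
  Wseg <- lapply(seq_len(J), function(j) neuron_template(wf, j))
  Wrev <- lapply(seq_len(E), function(e)
    matrix(vapply(Wseg, function(w) rev(w[e, ]), numeric(L)), L, J))
  n2 <- vapply(Wseg, function(w) sum(w^2), 0)
  b <- correlate_templates(r, Wrev)
  ins <- sweep(b, 2, n2 / 2 + theta)
  ev <- spikes$events
  del <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    j <- ev$neuron_id[i]; t0 <- ev$bin[i] + 1L
    w <- Wseg[[j]]
    if (!is.null(wf$derivatives)) {
      w <- w + ev$subbin_offset[i] * matrix(wf$derivatives$d_time[j, , ], E, L) +
        ev$amp_coef[i] * matrix(wf$derivatives$d_amp[j, , ], E, L) +
        ev$width_coef[i] * matrix(wf$derivatives$d_width[j, , ], E, L)
    }
    del[i] <- -sum(w * r[, t0:(t0 + L - 1L)]) - sum(w^2) / 2 + theta[j]
    ins[t0, j] <- -Inf   # that lattice site is occupied
  }
  list(max_gain = max(c(ins[is.finite(ins)], del, -Inf)),
       insert_gains = ins, delete_gains = del)
}

#' Coordinate-ascent MAP driver
#'
#' Runs the full inference round: waveform regression from the initial
#' spike trains, subset-selection pruning, noise estimation and two-stage
#' whitening (with waveform re-fit in the whitened space), plug-in prior
#' estimation p_j = n_j / N, and binary pursuit. By default a single
#' round is run; further rounds re-fit waveforms from the new spikes in
#' the whitened space (noise model, prior and support frozen after round
#' one so the objective is measured in a fixed metric) and re-run the
#' pursuit. The objective is recorded after each round and is
#' non-increasing.
#'
#' @param recording a raw [new_recording()].
#' @param init_spikes initial spike estimate (from [cluster_init()] or
#'   ground truth).
#' @param config a [bp_config()].
#' @return a list of class `bp_fit`: `spikes`, `waveforms_w` (whitened),
#'   `waveforms_raw`, `noise_model`, `theta`, `p`, `recording_w`,
#'   `objective_trace`, `config`.
#' @export
coordinate_ascent <- function(recording, init_spikes, config = bp_config()) {
  stopifnot(inherits(recording, "bp_recording"),
            inherits(init_spikes, "bp_spikes"))
  W <- estimate_waveforms(recording, init_spikes, taps = config$taps)
  resid <- compute_residual(recording, W, init_spikes)
  scale_e <- apply(resid, 1, stats::mad)
  W <- prune_waveforms(W, scale_e, a = config$prune_a)
  wp <- whiten_pipeline(recording, init_spikes, W,
                        window_bins = config$window_bins,
                        prune_a = config$prune_a)
  N <- init_spikes$n_bins
  counts <- tabulate(init_spikes$events$neuron_id, init_spikes$n_neurons)
  p <- pmin(pmax(counts / N, 1 / N), 0.499)
  theta <- compute_prior_weights(p, config$prior_multiplier)
  wf_w <- compute_derivatives(wp$waveforms_w)
  spikes <- process_blocks(wp$recording_w, wf_w, theta, config)
  obj <- bp_objective(wp$recording_w, wf_w, spikes, theta)
  trace <- obj
  if (config$rounds > 1) {
    for (round in 2:config$rounds) {
      wf_w <- estimate_waveforms(wp$recording_w, spikes, taps = config$taps,
                                 support_mask = wf_w$support_mask)
      wf_w <- compute_derivatives(wf_w)
      spikes <- process_blocks(wp$recording_w, wf_w, theta, config)
      obj <- bp_objective(wp$recording_w, wf_w, spikes, theta)
      trace <- c(trace, obj)
    }
  }
  structure(list(spikes = spikes, waveforms_w = wf_w, waveforms_raw = W,
                 noise_model = wp$noise_model, theta = theta, p = p,
                 recording_w = wp$recording_w, objective_trace = trace,
                 config = config),
            class = "bp_fit")
}

#' @export
print.bp_fit <- function(x, ...) {
  cat(sprintf("<bp_fit> %d spikes over %d neurons; objective %.2f\n",
              nrow(x$spikes$events), x$spikes$n_neurons,
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Re-run spike estimation with one neuron's prior scaled
#'
#' Recomputes theta for the given neuron as
#' `multiplier * log((1-p)/p)` (all other neurons keep the fit's penalty)
#' and re-runs block-wise binary pursuit on the stored whitened data.
#'
#' @param fit a `bp_fit`.
#' @param neuron_id neuron whose penalty is varied.
#' @param multiplier penalty multiplier (same scale as
#'   `config$prior_multiplier`).
#' @return the re-estimated [spike_events()] set.
#' @export
resolve_spikes <- function(fit, neuron_id, multiplier) {
  theta <- fit$theta
  theta[neuron_id] <- multiplier * log((1 - fit$p[neuron_id]) /
                                       fit$p[neuron_id])
  process_blocks(fit$recording_w, fit$waveforms_w, theta, fit$config)
}
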