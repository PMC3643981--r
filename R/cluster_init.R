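# Clustering-based initializer: threshold detection, snippet extraction
# over a neighborhood of electrodes, PCA, seeded k-means with Mahalanobis
# outlier rejection. Deliberately overlap-blind: temporally coincident
# spikes merge into one composite candidate whose feature vector falls far
# from every cluster and is discarded -- the classic failure mode the MAP
# solver then repairs.

#' Detect candidate spike events by thresholding
#'
#' Local negative extrema of each electrode exceeding
#' `threshold_multiplier` times that electrode's robust noise scale
#' (median absolute deviation based), deduplicated within a dead time of
#' one window across electrodes (the largest-amplitude candidate wins).
#'
#' @param recording a [new_recording()].
#' @param threshold_multiplier detection threshold in noise SDs (> 0).
#' @param window_ms dead-time / snippet window, ms.
#' @return data.frame with columns `electrode`, `bin` (0-based peak
#'   sample), `amplitude`.
#' @export
detect_candidates <- function(recording, threshold_multiplier = 4,
                              window_ms = 1.5) {
  stopifnot(threshold_multiplier > 0)
  V <- recording$data
  Lw <- ms_to_bins(window_ms, recording$sampling_rate_hz)
  cands <- list()
  for (e in seq_len(nrow(V))) {
    x <- V[e, ]
    scale <- stats::mad(x)
    if (scale == 0) stop(sprintf("electrode %d: constant trace, zero noise scale", e))
    thr <- -threshold_multiplier * scale
    n <- length(x)
    is_min <- x < thr &
      x <= c(Inf, x[-n]) & x < c(x[-1], Inf)  # strict on the right: one peak per plateau
    idx <- which(is_min)
    if (length(idx))
      cands[[length(cands) + 1L]] <-
        data.frame(electrode = e, bin = idx - 1L, amplitude = x[idx])
  }
  if (!length(cands))
    return(data.frame(electrode = integer(), bin = integer(),
                      amplitude = numeric()))
  cand <- do.call(rbind, cands)
  # global dead-time dedup, deepest trough first
  cand <- cand[order(cand$amplitude), ]
  keep <- logical(nrow(cand))
  taken <- integer()
  for (i in seq_len(nrow(cand))) {
    if (!any(abs(taken - cand$bin[i]) < Lw)) {
      keep[i] <- TRUE
      taken <- c(taken, cand$bin[i])
    }
  }
  out <- cand[keep, ]
  out <- out[order(out$bin), ]
  rownames(out) <- NULL
  out
}

# indices of the center electrode and its n nearest neighbors, by distance
# then index
neighbor_set <- function(geometry, center, n_neighbors) {
  d <- sqrt((geometry$x - geometry$x[center])^2 +
            (geometry$y - geometry$y[center])^2)
  ord <- order(d, seq_along(d))
  ord[seq_len(min(n_neighbors + 1L, length(ord)))]
}

#' Extract peak-aligned snippets around candidate events
#'
#' Each snippet concatenates a `window_ms` window (peak at the window
#' center) from the candidate's center electrode and its `n_neighbors`
#' nearest electrodes. Events too near the recording edges are skipped
#' with a warning.
#'
#' Snippets from different center electrodes are embedded into one fixed
#' global electrodes x taps frame (electrodes outside the neighborhood
#' zeroed), so every event lives in the same feature space.
#'
#' @param recording a [new_recording()].
#' @param events candidate table from [detect_candidates()].
#' @param window_ms snippet window, ms (1.5 ms gives 30 taps at 20 kHz).
#' @param n_neighbors electrodes beyond the center one.
#' @return list of class `bp_snippets`: `snippets` (events x features
#'   matrix), `events` (the retained candidates), `window_bins`,
#'   `center_tap`, `electrodes` (list of electrode sets per event).
#' @export
extract_snippets <- function(recording, events, window_ms = 1.5,
                             n_neighbors = 6) {
  V <- recording$data
  geom <- recording$geometry
  Lw <- ms_to_bins(window_ms, recording$sampling_rate_hz)
  center_tap <- Lw %/% 2 + 1L
  pre <- center_tap - 1L
  post <- Lw - center_tap
  ok <- events$bin - pre >= 0 & events$bin + post < ncol(V)
  if (any(!ok))
    warning(sprintf("%d events too near the recording edge were skipped",
                    sum(!ok)))
  events <- events[ok, , drop = FALSE]
  n_nb <- min(n_neighbors, nrow(geom) - 1L)
  E <- nrow(geom)
  snips <- matrix(0, nrow(events), E * Lw)
  elecs <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    es <- neighbor_set(geom, events$electrode[i], n_nb)
    idx <- (events$bin[i] - pre):(events$bin[i] + post) + 1L
    frame <- matrix(0, E, Lw)
    frame[es, ] <- V[es, idx, drop = FALSE]
    snips[i, ] <- as.numeric(t(frame))
    elecs[[i]] <- es
  }
  structure(list(snippets = snips, events = events, window_bins = Lw,
                 center_tap = center_tap, n_neighbors = n_nb,
                 electrodes = elecs),
            class = "bp_snippets")
}

#' Reduce snippet dimensionality by PCA
#'
#' Projects mean-centered snippets onto the top principal components;
#' score-column variances are non-increasing.
#'
#' @param snippets a `bp_snippets` or a plain matrix.
#' @param n_dims number of components.
#' @return scores matrix (events x n_dims) with attribute `rotation`.
#' @export
reduce_pca <- function(snippets, n_dims = 5) {
  X <- if (inherits(snippets, "bp_snippets")) snippets$snippets else snippets
  stopifnot(nrow(X) >= 2)
  if (n_dims > ncol(X)) stop("n_dims exceeds the feature dimension")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (n_dims > ncol(pc$x)) stop("n_dims exceeds the rank of the snippets")
  out <- pc$x[, seq_len(n_dims), drop = FALSE]
  attr(out, "rotation") <- pc$rotation[, seq_len(n_dims), drop = FALSE]
  attr(out, "center") <- pc$center
  out
}

# mean silhouette of a k-means labelling (small candidate counts only)
mean_silhouette <- function(features, labels) {
  if (length(unique(labels)) < 2) return(-Inf)
  if (requireNamespace("cluster", quietly = TRUE)) {
    mean(cluster::silhouette(labels, stats::dist(features))[, 3])
  } else {
    d <- as.matrix(stats::dist(features))
    s <- vapply(seq_along(labels), function(i) {
      a <- mean(d[i, labels == labels[i] & seq_along(labels) != i])
      bs <- vapply(setdiff(unique(labels), labels[i]),
                   function(k) mean(d[i, labels == k]), 0)
      b <- min(bs)
      if (!is.finite(a)) 0 else (b - a) / max(a, b)
    }, 0)
    mean(s)
  }
}

# shift a (taps x electrodes) centroid matrix by s bins (zeros shifted in)
shift_centroid <- function(m, s) {
  out <- matrix(0, nrow(m), ncol(m))
  src <- seq_len(nrow(m)) - s
  ok <- src >= 1 & src <= nrow(m)
  out[ok, ] <- m[src[ok], ]
  out
}

# best few alignment shifts of centroid a against target c, by inner
# product over +-max_shift bins
best_shifts <- function(target, a, max_shift, n_keep = 3) {
  ip <- vapply(-max_shift:max_shift, function(s)
    sum(target * shift_centroid(a, s)), 0)
  (-max_shift:max_shift)[order(-ip)][seq_len(n_keep)]
}

# Curate over-clustered groups in raw snippet space:
# 1. merge clusters whose centroids agree up to a time shift (one neuron
#    split by detection jitter),
# 2. drop clusters whose centroid is explained as a shifted sum of two
#    other centroids -- the "hallucinated neuron" that near-synchronous
#    spike superpositions create.
# Returns the curated label vector (0 = dropped).
curate_clusters <- function(snippets, labels, window_bins,
                            max_shift = 15, merge_tol = 0.25,
                            composite_tol = 0.3) {
  E <- ncol(snippets) / window_bins
  centroid <- function(lab, c_)
    matrix(colMeans(snippets[lab == c_, , drop = FALSE]), window_bins, E)
  # --- merge pass (repeat until stable) ---
  repeat {
    ids <- sort(unique(labels[labels > 0]))
    if (length(ids) < 2) break
    cent <- lapply(ids, centroid, lab = labels)
    nrm <- vapply(cent, function(m) sqrt(sum(m^2)), 0)
    merged <- FALSE
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i == j) next
        tgt <- as.numeric(cent[[i]])
        for (s in best_shifts(cent[[i]], cent[[j]], max_shift)) {
          x <- as.numeric(shift_centroid(cent[[j]], s))
          al <- sum(tgt * x) / sum(x^2)
          if (al < 0.7 || al > 1.4) next
          if (sqrt(sum((tgt - al * x)^2)) / nrm[i] < merge_tol) {
            labels[labels == ids[i]] <- ids[j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  # --- composite drop pass ---
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) >= 3) {
    cent <- lapply(ids, centroid, lab = labels)
    nrm <- vapply(cent, function(m) sqrt(sum(m^2)), 0)
    drop <- logical(length(ids))
    for (ci in order(-nrm)) {
      others <- which(!drop & seq_along(ids) != ci)
      if (length(others) < 2) next
      tgt <- as.numeric(cent[[ci]])
      best <- Inf
      for (ai in others) for (bi in others) {
        if (bi < ai) next
        sa <- best_shifts(cent[[ci]], cent[[ai]], max_shift)
        sb <- best_shifts(cent[[ci]], cent[[bi]], max_shift)
        for (s1 in sa) for (s2 in sb) {
          if (ai == bi && s1 == s2) next
          X <- cbind(as.numeric(shift_centroid(cent[[ai]], s1)),
                     as.numeric(shift_centroid(cent[[bi]], s2)))
          cf <- tryCatch(qr.solve(X, tgt), error = function(e) NULL)
          if (is.null(cf) || any(cf < 0.6) || any(cf > 1.4)) next
          best <- min(best, sqrt(sum((tgt - X %*% cf)^2)) / nrm[ci])
        }
      }
      if (best < composite_tol) drop[ci] <- TRUE
    }
    for (ci in which(drop)) labels[labels == ids[ci]] <- 0L
  }
  labels
}

#' Cluster events into putative neurons
#'
#' Seeded k-means in feature space with hard assignment. When raw
#' snippets are supplied the data are first deliberately over-clustered;
#' subclusters of one neuron (identical centroids up to a time shift)
#' are merged back, clusters whose centroid is a shifted sum of two
#' other centroids (composite waveforms of near-synchronous spike pairs)
#' are discarded -- an automated substitute for the human oversight that
#' would otherwise reject such "hallucinated neurons" -- and the `k`
#' largest surviving clusters become the neurons. Finally, points whose
#' robust (median/MAD) Mahalanobis distance from every cluster exceeds
#' `mahal_radius` are left unassigned; composite overlap waveforms that
#' did not form their own cluster land here.
#'
#' @param features score matrix from [reduce_pca()].
#' @param k number of clusters, or NULL for silhouette selection.
#' @param k_range candidate k values when `k` is NULL.
#' @param mahal_radius outlier radius (Mahalanobis distance, default
#'   sqrt of the 0.99 chi-square quantile at the feature dimension).
#' @param seed RNG seed for the k-means initialization.
#' @param snippets optional `bp_snippets` enabling the over-cluster /
#'   merge / composite-drop curation.
#' @return list: `labels` (0 = unassigned), `centers`, `k`, `silhouette`.
#' @export
cluster_events <- function(features, k = NULL, k_range = 2:8,
                           mahal_radius = NULL, seed = 1,
                           snippets = NULL) {
  stopifnot(is.matrix(features))
  if (!is.null(k) && k > nrow(features))
    stop("k exceeds the number of events")
  if (is.null(mahal_radius))
    mahal_radius <- sqrt(stats::qchisq(0.99, df = ncol(features)))
  fit_k <- function(kk) with_seed(seed,
    stats::kmeans(features, centers = kk, nstart = 10, iter.max = 100))
  if (is.null(k)) {
    k_range <- k_range[k_range <= nrow(features)]
    sil <- vapply(k_range, function(kk) mean_silhouette(features,
                                                        fit_k(kk)$cluster), 0)
    k <- k_range[which.max(sil)]
  }
  if (!is.null(snippets) && inherits(snippets, "bp_snippets") &&
      nrow(features) > 4 * (k + 4)) {
    k_over <- min(k + max(4L, k), nrow(features) - 1L)
    lab0 <- fit_k(k_over)$cluster
    lab0 <- curate_clusters(snippets$snippets, lab0, snippets$window_bins)
    sizes <- sort(table(lab0[lab0 > 0]), decreasing = TRUE)
    keep_ids <- as.integer(names(sizes))[seq_len(min(k, length(sizes)))]
    labels <- integer(nrow(features))
    for (i in seq_along(keep_ids))
      labels[lab0 == keep_ids[i]] <- i
    k <- length(keep_ids)
    centers <- t(vapply(seq_len(k), function(c_)
      colMeans(features[labels == c_, , drop = FALSE]),
      numeric(ncol(features))))
  } else {
    km <- fit_k(k)
    labels <- km$cluster
    centers <- km$centers
  }
  # Robust (median/MAD, diagonal) Mahalanobis rejection per cluster.
  # A plain covariance is masked by the very outliers we must reject:
  # composite overlap waveforms inflate the cluster covariance along
  # their own direction and sneak back inside the radius.
  md <- matrix(Inf, nrow(features), k)
  for (c_ in seq_len(k)) {
    pts <- features[labels == c_, , drop = FALSE]
    if (nrow(pts) <= ncol(features) + 1) next
    ctr <- apply(pts, 2, stats::median)
    sc <- apply(pts, 2, stats::mad)
    sc <- pmax(sc, 1e-6 * max(sc, 1e-300))
    md[, c_] <- sqrt(colSums(((t(features) - ctr) / sc)^2))
  }
  out_lab <- labels
  unassigned <- apply(md, 1, min) > mahal_radius
  out_lab[unassigned & is.finite(apply(md, 1, min))] <- 0L
  sil <- if (k > 1 && sum(out_lab > 0) > k)
    mean_silhouette(features[out_lab > 0, , drop = FALSE],
                    out_lab[out_lab > 0]) else NA_real_
  list(labels = out_lab, centers = centers, k = k, silhouette = sil)
}

#' Full clustering initializer
#'
#' Threshold detection, snippet extraction, PCA, clustering, and assembly
#' of the initial spike trains used to seed the MAP solver. Initial event
#' bins are placed so the snippet's center tap corresponds to waveform
#' alignment (bin = peak bin - (taps %/% 2)).
#'
#' @param recording a [new_recording()].
#' @param config a [bp_config()].
#' @param k number of neurons, or NULL for silhouette selection.
#' @param seed RNG seed.
#' @return list of class `bp_init`: `spikes` (a [spike_events()] set),
#'   `labels`, `candidates`, `rates_hz`, `p`, `k`, `silhouette`.
#' @export
cluster_init <- function(recording, config = bp_config(), k = NULL,
                         seed = 1) {
  window_ms <- config$taps * bin_spacing_ms(recording$sampling_rate_hz)
  cand <- detect_candidates(recording, config$threshold_multiplier,
                            window_ms)
  if (nrow(cand) < 2) stop("too few candidate events to cluster")
  sn <- extract_snippets(recording, cand, window_ms)
  feats <- reduce_pca(sn, n_dims = min(config$n_dims, nrow(sn$snippets) - 1))
  cl <- cluster_events(feats, k = k, seed = seed, snippets = sn)
  ev <- sn$events
  lab <- cl$labels
  pre <- sn$center_tap - 1L
  keep <- lab > 0
  bins <- ev$bin[keep] - pre
  df <- data.frame(neuron_id = lab[keep], bin = bins)
  df <- df[df$bin >= 0 & df$bin + config$taps <= recording$n_samples, ]
  df <- df[!duplicated(df[c("neuron_id", "bin")]), ]
  spikes <- spike_events(df, n_bins = recording$n_samples,
                         n_neurons = cl$k,
                         sampling_rate_hz = recording$sampling_rate_hz)
  counts <- tabulate(spikes$events$neuron_id, cl$k)
  structure(list(spikes = spikes, labels = lab, candidates = ev,
                 snippets = sn,
                 rates_hz = counts / (recording$n_samples /
                                      recording$sampling_rate_hz),
                 p = counts / recording$n_samples,
                 k = cl$k, silhouette = cl$silhouette),
            class = "bp_init")
}

#' @export
print.bp_init <- function(x, ...) {
  cat(sprintf("<bp_init> %d clusters, %d assigned spikes (%d candidates)\n",
              x$k, nrow(x$spikes$events), nrow(x$candidates)))
  invisible(x)
}
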