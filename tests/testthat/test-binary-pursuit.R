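test_that("prior weights are the scaled log odds against a spike", {
  # even odds: zero penalty
  expect_equal(compute_prior_weights(0.5), 0)
  # one spike per 500 bins (40 spikes/s at 20 kHz)
  expect_equal(compute_prior_weights(1 / 500), log(499), tolerance = 1e-12)
  expect_equal(log(499), 6.213, tolerance = 1e-3)
  # strictly decreasing in p; multiplier scales linearly
  p <- c(0.001, 0.01, 0.1, 0.4)
  th <- compute_prior_weights(p, multiplier = 2)
  expect_true(all(diff(th) < 0))
  expect_equal(th, 2 * compute_prior_weights(p))
  expect_error(compute_prior_weights(0), "0, 0.5")
  expect_error(compute_prior_weights(0.6), "0, 0.5")
})

test_that("delta_loglik matches its closed form and the objective oracle", {
  tw <- tiny_waveforms()
  w1 <- matrix(tw$wf$templates[1, , ], 4)
  L <- ncol(w1)
  n2 <- sum(w1^2)

  # residual equals the template: gain is +||w||^2/2 at theta 0
  r <- matrix(0, 4, 200)
  r[, 51:(50 + L)] <- w1
  expect_equal(delta_loglik(r, w1, theta = 0, bin = 50), n2 / 2)

  # zero residual: -||w||^2/2 - theta
  expect_equal(delta_loglik(matrix(0, 4, 200), w1, theta = 3, bin = 50),
               -n2 / 2 - 3)
  expect_error(delta_loglik(matrix(0, 4, 40), w1, 0, bin = 20), "footprint")

  # brute-force oracle: gain equals the objective difference of Eq-style
  # from-scratch evaluation, at random bins of a random residual
  theta <- c(4, 7)
  V <- withr::with_seed(21, matrix(stats::rnorm(4 * 500), 4, 500))
  base <- spikes_at(2, 300, 500, 2)
  for (bin in c(0, 57, 444)) {
    resid <- V - binpursuit:::predict_voltage(tw$wf, base, 500)
    gain <- delta_loglik(resid, w1, theta[1], bin)
    with_spike <- spikes_at(c(2, 1), c(300, bin), 500, 2)
    d_obj <- bp_objective(V, tw$wf, base, theta) -
      bp_objective(V, tw$wf, with_spike, theta)
    expect_equal(gain, d_obj, tolerance = 1e-8)
  }
})

test_that("the ridge Taylor correction recovers sub-bin shifts", {
  tw <- tiny_waveforms(amps = c(9, 7))
  wf <- compute_derivatives(tw$wf)
  D <- vapply(c("d_time", "d_amp", "d_width"),
              function(nm) as.numeric(wf$derivatives[[nm]][1, , ]),
              numeric(4 * wf$taps))

  # canonical template exactly: coefficients vanish
  w <- matrix(wf$templates[1, , ], 4)
  fx0 <- apply_variability_correction(w - w, D, gamma = 0)
  expect_lt(max(abs(fx0$coefs)), 1e-8)

  # template shifted by 0.3 bins: recovered tau near 0.3
  shifted <- t(apply(w, 1, function(row)
    binpursuit:::interp_taps(row, seq_along(row) - 0.3)))
  fx <- apply_variability_correction(shifted - w, D, gamma = 0)
  expect_equal(fx$coefs[1], 0.3, tolerance = 0.05)

  # ridge limit: gamma -> Inf shrinks coefficients to zero
  fxr <- apply_variability_correction(shifted - w, D, gamma = 1e12)
  expect_lt(max(abs(fxr$coefs)), 1e-6)

  # dense ridge-regression oracle
  resid <- withr::with_seed(22, matrix(stats::rnorm(length(w)), nrow(w)))
  gamma <- 2.5
  oracle <- solve(crossprod(D) + diag(gamma, 3), crossprod(D, as.numeric(resid)))
  fx2 <- apply_variability_correction(resid, D, gamma = gamma, clamp = Inf)
  expect_equal(fx2$coefs, as.numeric(oracle), tolerance = 1e-10)

  expect_error(apply_variability_correction(w, D[, c(1, 1)], gamma = 0),
               "gamma > 0")
})

test_that("greedy pursuit recovers isolated and synchronous spikes", {
  tw <- tiny_waveforms(amps = c(8, 8))
  wf <- compute_derivatives(tw$wf)
  L <- wf$taps
  theta <- c(6, 6)
  cfg <- bp_config(correct = character(0))

  # pure noise with a large penalty: no spikes
  noise <- withr::with_seed(23, matrix(stats::rnorm(4 * 4000), 4, 4000))
  res0 <- greedy_solve(noise, wf, theta = c(60, 60), cfg)
  expect_equal(nrow(res0$events), 0)

  # one rendered spike at SNR 8: exactly one event at the true bin
  sp <- spikes_at(1, 700, 4000, 2)
  rec <- render_recording(wf, sp, noise, 20000, tw$geom)
  res1 <- greedy_solve(rec$data, wf, theta, cfg)
  expect_equal(res1$events$neuron_id, 1L)
  expect_equal(res1$events$bin, 700L)

  # zero-offset synchronous pair with non-collinear templates: both found
  sync <- spikes_at(c(1, 2), c(1500, 1500), 4000, 2)
  rec2 <- render_recording(wf, sync, noise, 20000, tw$geom)
  res2 <- greedy_solve(rec2$data, wf, theta, cfg)
  hit <- res2$events[res2$events$bin > 1400 & res2$events$bin < 1600, ]
  expect_equal(sort(hit$neuron_id), c(1L, 2L))
  expect_equal(hit$bin, c(1500L, 1500L))

  # local optimality: an exhaustive post-hoc flip scan finds no gain
  sc <- scan_single_flips(rec2$data, wf, res2, theta)
  expect_lt(sc$max_gain, 1e-9 * max(template_norms(wf)))

  # determinism
  res2b <- greedy_solve(rec2$data, wf, theta, cfg)
  expect_identical(res2$events, res2b$events)

  expect_error(greedy_solve(matrix(c(1, NaN), 2, 10), wf, theta, cfg),
               "non-finite")
})

test_that("incremental gain bookkeeping matches from-scratch objectives", {
  # 4 neurons x 2000 bins; every accepted flip checked against Eq-style
  # re-evaluation of the full objective
  tw <- tiny_waveforms(n_electrodes = 4, amps = c(8, 7, 6.5, 7.5))
  wf <- tw$wf
  sp <- sample_spike_trains(rep(30, 4), 0.1, 20000, refractory_ms = 1.5,
                            seed = 31)
  noise <- sample_noise(4, 2000, ar_coef = 0, variance = 1, seed = 32)
  rec <- render_recording(wf, sp, noise, 20000, tw$geom)
  theta <- compute_prior_weights(rep(30 / 20000, 4), multiplier = 6)
  cfg <- bp_config(correct = character(0))
  cfg$track <- TRUE
  res <- greedy_solve(rec$data, wf, theta, cfg)
  flips <- attr(res, "flips")
  trace <- attr(res, "objective_trace")
  expect_gt(nrow(flips), 3)

  # objective strictly decreases at every accepted flip
  expect_true(all(diff(trace) < 0))

  # replay the flips, recomputing the objective from scratch each time
  cur <- data.frame(neuron_id = integer(), bin = integer())
  for (i in seq_len(nrow(flips))) {
    if (flips$action[i] == "insert") {
      cur <- rbind(cur, data.frame(neuron_id = flips$neuron_id[i],
                                   bin = flips$bin[i]))
    } else {
      drop <- which(cur$neuron_id == flips$neuron_id[i] &
                    cur$bin == flips$bin[i])
      cur <- cur[-drop, , drop = FALSE]
    }
    obj <- bp_objective(rec$data, wf,
                        spikes_at(cur$neuron_id, cur$bin, 2000, 4), theta)
    expect_equal(trace[i + 1], obj, tolerance = 1e-8)
    # the accepted gain equals the achieved objective decrease
    expect_equal(trace[i] - trace[i + 1], flips$gain[i], tolerance = 1e-8)
  }

  # final event set is a local optimum
  sc <- scan_single_flips(rec$data, wf, res, theta)
  expect_lt(sc$max_gain, 1e-9 * max(template_norms(wf)))
})

test_that("block processing is transparent to block size", {
  tw <- tiny_waveforms(amps = c(8, 8))
  wf <- compute_derivatives(tw$wf)
  cfg <- bp_config(block_s = 0.05)  # 1000-bin blocks
  theta <- c(7, 7)

  # empty recording: empty result
  quiet <- new_recording(0.01 * withr::with_seed(41,
    matrix(stats::rnorm(4 * 3000), 4, 3000)), 20000, tw$geom)
  expect_equal(nrow(process_blocks(quiet, wf, c(60, 60), cfg)$events), 0)

  # spikes straddling block boundaries are recovered exactly once and
  # identically to a single-block run
  bins <- c(120, 985, 1005, 1992, 2500)  # several near 1000/2000 boundaries
  sp <- spikes_at(c(1, 2, 1, 2, 1), bins, 3000, 2)
  noise <- withr::with_seed(42, matrix(stats::rnorm(4 * 3000), 4, 3000))
  rec <- render_recording(wf, sp, noise, 20000, tw$geom)
  multi <- process_blocks(rec, wf, theta, cfg)
  single <- process_blocks(rec, wf, theta, bp_config(block_s = 0.2))
  expect_equal(multi$events[c("neuron_id", "bin")],
               single$events[c("neuron_id", "bin")])
  expect_setequal(multi$events$bin, bins)

  expect_error(process_blocks(rec, wf, theta, bp_config(block_s = 0.002)),
               "block length")
})

test_that("raising the prior multiplier weakly decreases the spike count", {
  sim <- simulate_recording(n_electrodes = 4, duration_s = 6, n_neurons = 2,
                            snr = 6, rates = 15, seed = 51)
  fit <- coordinate_ascent(sim$recording, sim$spikes, bp_config())
  counts <- sapply(c(1, 3, 6, 12, 25), function(m)
    nrow(resolve_spikes(fit, 1, m)$events) )
  expect_true(all(diff(counts) <= 0))
})

test_that("coordinate ascent descends across rounds and finds fixed points", {
  sim <- simulate_recording(n_electrodes = 4, duration_s = 8, n_neurons = 2,
                            snr = 8, rates = 10, seed = 61)
  fit2 <- coordinate_ascent(sim$recording, sim$spikes,
                            bp_config(rounds = 3))
  expect_true(all(diff(fit2$objective_trace) <= 1e-6))

  # noiseless single-spike data: round one attains the oracle, further
  # rounds change nothing
  tw <- tiny_waveforms(amps = c(8, 7))
  sp <- spikes_at(c(1, 2), c(300, 900), 2000, 2)
  rec <- render_recording(tw$wf, sp,
                          0.02 * withr::with_seed(62,
                            matrix(stats::rnorm(4 * 2000), 4, 2000)),
                          20000, tw$geom)
  f1 <- coordinate_ascent(rec, sp, bp_config(rounds = 1,
                                             correct = character(0)))
  f2 <- coordinate_ascent(rec, sp, bp_config(rounds = 2,
                                             correct = character(0)))
  expect_identical(f1$spikes$events[c("neuron_id", "bin")],
                   f2$spikes$events[c("neuron_id", "bin")])
})
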