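test_that("waveform templates obey amplitude, decay and peak conventions", {
  geom <- electrode_grid(4)

  # zero amplitude: all-zero tensor
  w0 <- make_waveform(geom, c(0, 0), amplitude = 0)
  expect_true(all(w0 == 0))

  # negative-going peak of -A on the electrode at the neuron position
  w <- make_waveform(geom, c(geom$x[2], geom$y[2]), amplitude = 5)
  expect_equal(min(w[2, ]), -5)
  expect_equal(sum(w == -5), 1)  # exactly one global extremum sample

  # exponential spatial decay: electrodes at d and 2d
  line <- data.frame(x = c(0, 1, 2), y = 0)
  wl <- make_waveform(line, c(0, 0), amplitude = 4, lambda = 0.7)
  expect_equal(min(wl[2, ]) / min(wl[1, ]), exp(-1 / 0.7), tolerance = 1e-12)
  expect_equal(min(wl[3, ]) / min(wl[2, ]), exp(-1 / 0.7), tolerance = 1e-12)

  expect_error(make_waveform(geom, c(NA, 0), amplitude = 1), "non-finite")
  expect_error(make_waveform(geom, c(0, 0), amplitude = -1), ">= 0")
})

test_that("Bernoulli spike trains respect rate, refractoriness and seeding", {
  # zero rate: empty train
  s0 <- sample_spike_trains(0, duration_s = 1, sampling_rate_hz = 20000,
                            seed = 1)
  expect_equal(nrow(s0$events), 0)

  expect_error(sample_spike_trains(30000, 1, 20000, seed = 1),
               "below the sampling rate")

  # seeded determinism
  a <- sample_spike_trains(c(10, 20), 5, 20000, seed = 7)
  b <- sample_spike_trains(c(10, 20), 5, 20000, seed = 7)
  expect_identical(a$events, b$events)

  # 40 spikes/s at 20 kHz: about one spike per 500 bins
  s <- sample_spike_trains(40, duration_s = 120, sampling_rate_hz = 20000,
                           refractory_ms = 0, seed = 3)
  gaps <- diff(sort(s$events$bin))
  expect_equal(mean(gaps), 500, tolerance = 0.05)
  expect_equal(expected_isi_bins(40, 20000), 500)

  # refractoriness: no ISI below the refractory period
  sr <- sample_spike_trains(80, 30, 20000, refractory_ms = 2, seed = 5)
  expect_true(all(diff(sort(sr$events$bin)) >= 2e-3 * 20000))

  # empirical rate within 3 standard errors of the requested rate
  dur <- 60
  s60 <- sample_spike_trains(10, dur, 20000, refractory_ms = 1.5, seed = 9)
  n <- nrow(s60$events)
  # refractory thinning correction: expected rate r / (1 + r * t_ref)
  expected <- 10 / (1 + 10 * 1.5e-3) * dur
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("synchrony injection duplicates partner spikes", {
  sync <- list(list(pair = c(1, 2), prob = 1, jitter_bins = 0))
  s <- sample_spike_trains(c(20, 0), 10, 20000, refractory_ms = 1.5,
                           sync_spec = sync, seed = 11)
  a <- s$events$bin[s$events$neuron_id == 1]
  b <- s$events$bin[s$events$neuron_id == 2]
  expect_true(all(a %in% b))  # every A spike has a coincident B spike
})

test_that("separable noise field matches its specified covariance", {
  # zero variance: all zeros
  z <- sample_noise(2, 100, variance = 0, seed = 1)
  expect_true(all(z == 0))

  expect_error(sample_noise(2, 100, ar_coef = 1.2, seed = 1), "unit circle")

  n <- 2e5
  geom <- electrode_grid(4)
  # AR(1) lag-1 autocorrelation
  x <- sample_noise(1, n, ar_coef = 0.5, seed = 2)
  r1 <- stats::cor(x[1, -1], x[1, -n])
  expect_equal(r1, 0.5, tolerance = 0.01)

  # spatial correlation: pick spatial_length so adjacent electrodes
  # correlate at 0.6
  sl <- -1 / log(0.6)
  y <- sample_noise(4, n, geom, ar_coef = 0, spatial_length = sl,
                    variance = 2, seed = 3)
  expect_equal(stats::cor(y[1, ], y[2, ]), 0.6, tolerance = 0.02)

  # full covariance Frobenius convergence
  emp <- tcrossprod(y) / n
  target <- 2 * exp(-as.matrix(stats::dist(geom)) / sl)
  expect_lt(norm(emp - target, "F") / norm(target, "F"), 0.05)

  # seeded determinism
  expect_identical(sample_noise(2, 50, ar_coef = 0.3, seed = 4),
                   sample_noise(2, 50, ar_coef = 0.3, seed = 4))
})

test_that("rendering is an exact linear superposition", {
  tw <- tiny_waveforms()
  L <- tw$wf$taps
  noise <- matrix(0, 4, 2000)

  # no spikes: identical to the noise input
  empty <- spikes_at(integer(), integer(), 2000, 2)
  r0 <- render_recording(tw$wf, empty, noise, 20000, tw$geom)
  expect_identical(r0$data, noise)

  # one spike, zero noise: template placed at the bin, zeros elsewhere
  s1 <- spikes_at(1, 100, 2000, 2)
  r1 <- render_recording(tw$wf, s1, noise, 20000, tw$geom)
  expect_equal(r1$data[, 101:(100 + L)],
               matrix(tw$wf$templates[1, , ], 4, L))
  expect_true(all(r1$data[, -(101:(100 + L))] == 0))

  # linearity: overlapping spikes render as the sum of single renders
  s2 <- spikes_at(2, 110, 2000, 2)
  s12 <- spikes_at(c(1, 2), c(100, 110), 2000, 2)
  r2 <- render_recording(tw$wf, s2, noise, 20000, tw$geom)
  r12 <- render_recording(tw$wf, s12, noise, 20000, tw$geom)
  expect_equal(r12$data, r1$data + r2$data)

  # spike too close to the end: out-of-range error
  expect_error(render_recording(tw$wf, spikes_at(1, 1990, 2000, 2),
                                noise, 20000, tw$geom), "too close")
})

test_that("simulated recordings are reproducible under a fixed seed", {
  a <- simulate_recording(n_electrodes = 4, duration_s = 2, n_neurons = 2,
                          seed = 5)
  b <- simulate_recording(n_electrodes = 4, duration_s = 2, n_neurons = 2,
                          seed = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$spikes$events, b$spikes$events)
})
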