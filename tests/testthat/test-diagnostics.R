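test_that("cross-correlograms measure conditional rates correctly", {
  dur <- 100
  # independent homogeneous Poisson trains: flat CCF at train b's rate
  a <- withr::with_seed(1, sort(stats::runif(1000, 0, dur)))
  b <- withr::with_seed(2, sort(stats::runif(1500, 0, dur)))
  ccf <- cross_correlogram(a, b, window_ms = 10, bin_ms = 1,
                           duration_s = dur)
  rate_b <- length(b) / dur
  # 3 sigma Poisson band per bin: counts ~ Poisson(n_a * rate_b * bin)
  lam <- length(a) * rate_b * 1e-3
  band <- 3 * sqrt(lam) / (length(a) * 1e-3)
  expect_true(all(abs(ccf$rate_hz - rate_b) < band))
  expect_equal(ccf$baseline_hz, rate_b)

  # shifted copy of a sparse train: single peak at the +2.2 ms lag bin
  sparse <- seq(0.5, dur - 0.5, by = 0.5)
  ccf2 <- cross_correlogram(sparse, sparse + 2.2e-3, window_ms = 10,
                            bin_ms = 1, duration_s = dur)
  expect_equal(ccf2$lags_ms[which.max(ccf2$rate_hz)], 2.5)
  expect_equal(sum(ccf2$counts > 0), 1)

  # time-reversal symmetry after rate renormalization
  ccf_ab <- cross_correlogram(a, b, 10, 1, dur)
  ccf_ba <- cross_correlogram(b, a, 10, 1, dur)
  expect_equal(ccf_ab$counts, rev(ccf_ba$counts))

  # empty reference: defined-empty
  ccf0 <- cross_correlogram(numeric(), b, 10, 1, dur)
  expect_equal(ccf0$n_ref, 0)
  expect_true(all(ccf0$counts == 0))
  expect_error(cross_correlogram(a, b, 10, 3, dur), "multiple")
})

test_that("the artifact index quantifies the zero-lag notch", {
  lags <- seq(-9.75, 9.75, by = 0.5)
  flat <- structure(list(lags_ms = lags, rate_hz = rep(20, length(lags)),
                         baseline_hz = 20, n_ref = 100, bin_ms = 0.5),
                    class = "bp_ccf")
  expect_equal(ccf_artifact_index(flat), 0)

  # central bins at half the flank rate, flank at baseline: index 0.5
  notched <- flat
  notched$rate_hz[abs(lags) <= 1] <- 10
  expect_equal(ccf_artifact_index(notched, notch_ms = 1, flank_ms = 5), 0.5)

  # scale invariance
  scaled <- notched
  scaled$rate_hz <- scaled$rate_hz * 7
  scaled$baseline_hz <- scaled$baseline_hz * 7
  expect_equal(ccf_artifact_index(scaled), ccf_artifact_index(notched))

  zero <- flat
  zero$baseline_hz <- 0
  expect_true(is.na(ccf_artifact_index(zero)))
  expect_error(ccf_artifact_index(flat, notch_ms = 5, flank_ms = 2), "flank")
})

test_that("deleting near-synchronous spikes raises the artifact index monotonically", {
  dur <- 200
  with_seed_trains <- withr::with_seed(7, {
    a <- sort(stats::runif(2000, 0, dur))
    # b: independent spikes plus true coincidences with a
    b_ind <- sort(stats::runif(1500, 0, dur))
    b_sync <- a[stats::runif(2000) < 0.25]
    list(a = a, b = sort(c(b_ind, b_sync)), b_sync = b_sync)
  })
  idx <- sapply(c(0, 0.5, 1), function(f) {
    # delete a fraction f of the coincident spikes from b
    drop <- with_seed_trains$b_sync[seq_len(round(f * length(with_seed_trains$b_sync)))]
    b <- setdiff(with_seed_trains$b, drop)
    ccf_artifact_index(cross_correlogram(with_seed_trains$a, b, 10, 0.5, dur))
  })
  expect_true(all(diff(idx) > 0))
})

test_that("contamination rate matches its occupancy-corrected definition", {
  # worked example: in-window rate exactly half the out-of-window rate.
  # 100 base spikes 12.6 ms apart over 1.26 s with r = 2 ms windows;
  # 10 extra spikes 1 ms after a base spike extend those windows to 3 ms:
  # occupancy 0.21 s, rates (10/0.21) / (100/1.05) = 1/2.
  base <- (0:99) * 0.0126
  extra <- base[1:10] + 0.001
  train <- sort(c(base, extra))
  expect_equal(contamination_rate(train, refractory_ms = 2,
                                  duration_s = 1.26), 50)

  # all ISIs above the refractory period: 0%
  expect_equal(contamination_rate(base, 2, duration_s = 1.26), 0)

  # homogeneous Poisson: memorylessness gives ~100%
  pois <- withr::with_seed(8, sort(stats::runif(5000, 0, 100)))
  expect_equal(contamination_rate(pois, refractory_ms = 2,
                                  duration_s = 100), 100, tolerance = 0.15)

  expect_true(is.na(contamination_rate(c(1), 2, 10)))
})

test_that("spike matching maximizes hits one-to-one within tolerance", {
  expect_equal(match_spikes(1:5, 1:5, 0)$error_rate, 0)
  m0 <- match_spikes(numeric(), 1:4, 1)
  expect_equal(m0$error_rate, 100)
  expect_equal(m0$misses, 4)

  # matched count equals the optimal bipartite assignment (oracle)
  for (rep in 1:20) {
    pair <- withr::with_seed(100 + rep, {
      tru <- sort(stats::runif(sample(3:10, 1), 0, 20))
      est <- sort(c(tru + stats::rnorm(length(tru), 0, 0.4),
                    stats::runif(sample(0:3, 1), 0, 20)))
      list(tru = tru, est = est)
    })
    m <- match_spikes(pair$est, pair$tru, tol = 0.5)
    expect_equal(m$hits, brute_force_hits(pair$est, pair$tru, 0.5))
  }
})

test_that("sensitivity derivative matches a dense multiplier sweep", {
  # synthetic detector: count(m) = round(400 * m^-0.8)
  count_fn <- function(m) round(400 * m^-0.8)
  mult <- c(0.3, 0.7, 1, 1.4, 3)
  sa <- sensitivity_analysis(count_fn, mult, default = 1)
  expect_true(all(diff(sa$counts) <= 0))
  dense <- exp(seq(log(0.3), log(3), length.out = 200))
  slope <- stats::coef(stats::lm(log(sapply(dense, count_fn)) ~ log(dense)))[2]
  expect_equal(sa$sensitivity, abs(unname(slope)), tolerance = 0.1)
  expect_warning(sensitivity_analysis(function(m) 0, mult, default = 1),
                 "zero spike count")
})

test_that("power-law fits recover exact relations and match the OLS oracle", {
  x <- c(0.1, 0.5, 1, 2, 7)
  y <- 2 * x^1.5
  pl <- fit_powerlaw(x, y)
  expect_equal(pl$exponent, 1.5, tolerance = 1e-10)
  expect_equal(pl$prefactor, 2, tolerance = 1e-10)
  expect_equal(pl$r_squared, 1, tolerance = 1e-10)
  # monotone predictor for positive exponents
  grid <- seq(0.05, 10, length.out = 50)
  expect_true(all(diff(pl$predict(grid)) > 0))

  # closed-form two-parameter OLS oracle on noisy data
  yn <- withr::with_seed(9, y * exp(stats::rnorm(5, 0, 0.3)))
  pln <- fit_powerlaw(x, yn)
  lx <- log(x); ly <- log(yn)
  beta <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  alpha <- mean(ly) - beta * mean(lx)
  expect_equal(pln$exponent, beta, tolerance = 1e-10)
  expect_equal(pln$prefactor, exp(alpha), tolerance = 1e-10)

  expect_error(fit_powerlaw(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_powerlaw(c(0, 1, 2), c(1, 1, 1)), "> 0")
})

test_that("scalar detection reproduces the Gaussian signal-detection closed forms", {
  snr <- 3; p <- 0.2
  thr <- seq(-2, 5, by = 0.05)
  sim <- scalar_detection_sim(snr, p, thr, n_trials = 4e4, seed = 10)
  # threshold -> -inf: everything detected
  low <- scalar_detection_sim(snr, p, -50, n_trials = 1e4, seed = 11)
  expect_equal(low$detections, 1)

  # error-minimizing threshold: mu/2 + log((1-p)/p)/mu
  thr_opt <- snr / 2 + log((1 - p) / p) / snr
  emp_opt <- sim$threshold[which.min(sim$errors)]
  expect_lt(abs(emp_opt - thr_opt), 0.25)

  # error at the optimum matches the Phi-based closed form within 3 MC SE
  err_closed <- p * stats::pnorm(thr_opt - snr) +
    (1 - p) * stats::pnorm(thr_opt, lower.tail = FALSE)
  emp_err <- sim$errors[which.min(abs(sim$threshold - thr_opt))]
  se <- sqrt(err_closed * (1 - err_closed) / 4e4)
  expect_lt(abs(emp_err - err_closed), 3 * se + 0.002)
})
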