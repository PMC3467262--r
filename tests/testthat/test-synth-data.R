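test_that("evaluate_rate reproduces the lobe closed form", {
  ep <- default_epoch()
  flat <- rate_profile(12)
  expect_equal(evaluate_rate(flat, c(0, 250, 1999), ep), rep(12, 3))

  prof <- rate_profile(10, on_amp = 50, on_latency = 80, on_tau = 60)
  onset_ms <- ep$onset * 1000
  # peak at latency by construction
  expect_equal(evaluate_rate(prof, onset_ms + 80, ep), 10 + 50)
  # one decay constant later the lobe has fallen to A/e
  expect_equal(evaluate_rate(prof, onset_ms + 80 + 60, ep),
               10 + 50 / exp(1), tolerance = 1e-12)
  # before the rise starts, baseline only
  expect_equal(evaluate_rate(prof, onset_ms + 60, ep), 10)
  expect_true(all(evaluate_rate(prof, seq(0, 2000, by = 0.5), ep) >= 0))
})

test_that("cell_spec enforces class/lobe consistency", {
  expect_error(cell_spec("OFF", rate_profile(5, on_amp = 10)), "inconsistent")
  expect_error(cell_spec("ON-OFF", rate_profile(5, on_amp = 10)), "inconsistent")
  expect_s3_class(cell_spec("OFF", rate_profile(5, off_amp = 10)), "cell_spec")
})

test_that("simulate_spike_train is a reproducible Poisson process", {
  ep <- stimulus_epoch(block_duration = 10)
  sp <- cell_spec("ON-transient", rate_profile(100, on_amp = 1e-9),
                  n_blocks = 1, seed = 11)
  # constant 100 Hz over 10 s: count within 3 SD of 1000
  n <- length(simulate_spike_train(sp, ep)$blocks[[1]])
  expect_lt(abs(n - 1000), 3 * sqrt(1000))

  # determinism: identical spec => bit-identical timestamps
  sp5 <- cell_spec("ON-OFF", rate_profile(10, on_amp = 80, off_amp = 80),
                   n_blocks = 5, seed = 42)
  t1 <- simulate_spike_train(sp5, default_epoch())
  t2 <- simulate_spike_train(sp5, default_epoch())
  expect_identical(t1$blocks, t2$blocks)

  # zero rate => empty train
  sp0 <- cell_spec("ON-transient", rate_profile(0, on_amp = 1e-12),
                   n_blocks = 2, seed = 1)
  expect_identical(lengths(simulate_spike_train(sp0, default_epoch())$blocks),
                   c(0L, 0L))
  # needs the 100 ms pre-onset baseline
  expect_error(simulate_spike_train(sp5, stimulus_epoch(onset = 0.05,
                                                        offset = 0.35)),
               "pre-onset")
})

test_that("constant-rate counts calibrate across 100 seeds", {
  ep <- stimulus_epoch(block_duration = 5)
  counts <- vapply(1:100, function(s) {
    sp <- cell_spec("ON-transient", rate_profile(40, on_amp = 1e-9),
                    n_blocks = 1, seed = s)
    length(simulate_spike_train(sp, ep)$blocks[[1]])
  }, numeric(1))
  mu <- 40 * 5
  # mean of 100 Poisson(200) draws: SE = sqrt(200/100)
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(mu / 100))
  expect_gt(stats::var(counts), mu * 0.6)   # dispersion is Poisson-like
  expect_lt(stats::var(counts), mu * 1.5)
})

test_that("simulate_raw_trace inserts templates at known samples", {
  expect_error(simulate_raw_trace(spike_train(list(0.1), 1), -5), "positive")
  # empty train, zero noise -> all-zero trace
  tr0 <- simulate_raw_trace(spike_train(list(numeric(0)), 1), 50, noise_sd = 0)
  expect_true(all(tr0$samples == 0))
  # 10 noise-free spikes: 10 negative extrema at the inserted samples
  times <- seq(0.05, 0.95, by = 0.1)
  tr <- simulate_raw_trace(spike_train(list(times), 1), 80, noise_sd = 0)
  mins <- which(tr$samples < -79.9)
  expect_length(mins, 10)
  expect_equal((mins - 1) / tr$sampling_rate, times, tolerance = 1e-9)
})

test_that("simulate_erg matches its closed form", {
  # flat spec -> flat trace
  f <- simulate_erg(erg_spec(a_amp = 0, b_amp = 0, noise_sd = 0))
  expect_true(all(f$voltage == 0))
  # noise-free maximum sits at the b-wave latency
  tr <- simulate_erg(erg_spec(a_amp = 100, b_amp = 300, b_latency = 100,
                              noise_sd = 0))
  expect_equal(tr$time_ms[which.max(tr$voltage)], 100)
  # trough-to-peak span equals the analytic extrema of the two-lobe sum
  spec <- erg_spec(a_amp = 100, b_amp = 300, noise_sd = 0)
  tg <- seq(0, 300, by = 0.01)
  vg <- -spec$a_amp * exp(-((tg - spec$a_latency) / spec$a_width)^2 / 2) +
    spec$b_amp * exp(-((tg - spec$b_latency) / spec$b_width)^2 / 2)
  span <- max(vg) - min(vg)
  expect_equal(span, 400, tolerance = 0.01)  # lobes barely overlap
  tr2 <- simulate_erg(spec)
  expect_equal(max(tr2$voltage) - min(tr2$voltage), span, tolerance = 1e-3)
  expect_error(erg_spec(a_latency = 80, b_latency = 60), "precede")
})

test_that("flicker trains follow the first-order low-pass law", {
  sp <- cell_spec("ON-transient", rate_profile(30, on_amp = 1e-9),
                  n_blocks = 2, seed = 3)
  expect_error(simulate_flicker_train(sp, -1), "positive")
  # at the cutoff the effective depth is 1/sqrt(2) of maximum
  tr <- simulate_flicker_train(sp, frequency = 8, cutoff = 8, depth = 1)
  expect_equal(attr(tr, "modulation_depth"), 1 / sqrt(2))
  # far below cutoff, nearly full depth
  lo <- simulate_flicker_train(sp, frequency = 0.5, cutoff = 8, depth = 0.9)
  expect_gt(attr(lo, "modulation_depth"), 0.9 * 0.995)
  # zero depth -> stationary train with ~r0 * duration spikes
  st <- simulate_flicker_train(sp, 2, depth = 0)
  n <- sum(lengths(st$blocks))
  expect_lt(abs(n - 30 * 10 * 2), 4 * sqrt(600))
})
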