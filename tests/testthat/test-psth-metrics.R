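test_that("build_psth converts pooled counts to rates and conserves spikes", {
  ep <- default_epoch()
  # 5 blocks, one spike each in the same 1 ms bin -> 1000 Hz in that bin
  tr <- spike_train(rep(list(0.2505), 5), 2)
  p <- build_psth(tr, ep)
  expect_equal(max(p$rates), 1000)
  expect_equal(sum(p$rates > 0), 1)

  # empty input warns and yields all-zero bins
  expect_warning(p0 <- build_psth(spike_train(list(numeric(0)), 2), ep),
                 "no spikes")
  expect_true(all(p0$rates == 0))

  # exact count conservation: rate * bin * n_blocks is integer per bin
  sp <- cell_spec("ON-OFF", rate_profile(15, on_amp = 120, off_amp = 120),
                  n_blocks = 5, seed = 9)
  tr2 <- simulate_spike_train(sp, ep)
  p2 <- build_psth(tr2, ep)
  counts <- p2$rates * (p2$bin_width_ms / 1000) * p2$n_blocks
  expect_equal(counts, round(counts), tolerance = 1e-9)
  expect_equal(sum(counts), sum(lengths(tr2$blocks)))

  # constant-rate train recovers its mean rate
  ep10 <- stimulus_epoch(block_duration = 10)
  spc <- cell_spec("ON-transient", rate_profile(100, on_amp = 1e-9),
                   n_blocks = 3, seed = 2)
  pc <- build_psth(simulate_spike_train(spc, ep10), ep10)
  expect_equal(mean(pc$rates), 100, tolerance = 0.05)
})

test_that("smooth_psth is a mass-preserving Gaussian convolution", {
  # impulse -> Gaussian profile with the requested sigma
  p <- psth_from_rates(c(rep(0, 500), 1000, rep(0, 499)))
  sm <- smooth_psth(p, 25)
  expect_equal(sm$rates[501], 1000 * stats::dnorm(0, sd = 25) /
                 sum(stats::dnorm(seq(-100, 100), sd = 25)), tolerance = 1e-6)
  expect_equal(sm$rates[501 + 25], sm$rates[501] * exp(-0.5), tolerance = 1e-3)
  # constant PSTH unchanged in the interior
  pc <- psth_from_rates(rep(40, 400))
  expect_equal(smooth_psth(pc, 25)$rates[150:250], rep(40, 101))
  # total rate mass preserved to 0.1% (reflected boundaries)
  set.seed(1)
  pr <- psth_from_rates(stats::rpois(2000, 5) * 10)
  expect_equal(sum(smooth_psth(pr, 25)$rates), sum(pr$rates),
               tolerance = 1e-3)
  expect_error(smooth_psth(pc, 0), "positive")
})

test_that("estimate_baseline averages the 100 ms pre-onset window", {
  ep <- default_epoch()
  expect_equal(estimate_baseline(psth_from_rates(rep(20, 2000)), ep), 20)
  r <- rep(50, 2000); r[1:100] <- 0
  expect_equal(estimate_baseline(psth_from_rates(r), ep), 0)
  expect_error(estimate_baseline(psth_from_rates(rep(1, 2000)),
                                 stimulus_epoch(onset = 0.1001,
                                                offset = 0.4),
                                 window_ms = 150), "150")
  # simulated 15 Hz baseline, 5 blocks: within Poisson error of 15
  sp <- cell_spec("ON-transient", rate_profile(15, on_amp = 100),
                  n_blocks = 5, seed = 21)
  p <- build_psth(simulate_spike_train(sp, ep), ep)
  # SE of the mean over 0.1 s x 5 blocks at 15 Hz: sqrt(7.5)/0.5 Hz
  expect_lt(abs(estimate_baseline(p, ep) - 15), 4 * sqrt(15 * 0.1 * 5) / 0.5)
})

test_that("ON metrics recover the generating profile exactly in the limit", {
  ep <- default_epoch()
  prof <- rate_profile(10, on_amp = 50, on_latency = 80, on_tau = 60)
  p <- analytic_psth(prof, ep)
  b <- estimate_baseline(p, ep)
  m <- extract_on_metrics(p, b, ep)
  expect_equal(m$A1, 50, tolerance = 0.05)
  expect_equal(m$L1, 80, tolerance = 0.05)
  expect_equal(m$A1tau2, 60, tolerance = 0.05)
  expect_true(m$responsive)
  expect_false(m$censored)

  # constant PSTH: zero amplitude, flagged non-responsive
  pc <- psth_from_rates(rep(30, 2000))
  mc <- extract_on_metrics(pc, 30, ep)
  expect_equal(mc$A1, 0)
  expect_false(mc$responsive)
})

test_that("OFF metrics mirror ON metrics at stimulus offset", {
  ep <- default_epoch()
  prof <- rate_profile(10, off_amp = 40, off_latency = 90, off_tau = 50)
  p <- analytic_psth(prof, ep)
  b <- estimate_baseline(p, ep)
  m <- extract_off_metrics(p, b, ep)
  expect_equal(m$A2, 40, tolerance = 0.05)
  expect_equal(m$L2, 90, tolerance = 0.05)
  expect_equal(m$A2tau2, 50, tolerance = 0.05)
  # the same cell has no ON response
  mon <- extract_on_metrics(p, b, ep)
  expect_lt(mon$A1, 0.05 * 40)
})

test_that("A1 is invariant to a constant added rate", {
  ep <- default_epoch()
  prof <- rate_profile(5, on_amp = 60, on_latency = 70, on_tau = 50)
  p1 <- analytic_psth(prof, ep)
  p2 <- p1; p2$rates <- p2$rates + 35
  m1 <- extract_on_metrics(p1, estimate_baseline(p1, ep), ep)
  m2 <- extract_on_metrics(p2, estimate_baseline(p2, ep), ep)
  expect_equal(m1$A1, m2$A1, tolerance = 1e-12)
  expect_equal(m1$L1, m2$L1)
})

test_that("extracted A1 is monotone in the generating amplitude", {
  ep <- default_epoch()
  amps <- c(20, 40, 80, 160)
  a1 <- vapply(amps, function(a) {
    prof <- rate_profile(10, on_amp = a, on_latency = 80, on_tau = 60)
    p <- analytic_psth(prof, ep)
    extract_on_metrics(p, estimate_baseline(p, ep), ep)$A1
  }, numeric(1))
  expect_true(all(diff(a1) > 0))
})

test_that("parameter recovery from simulated trains at 5 blocks", {
  ep <- default_epoch()
  # ground-truth response duration 150 ms
  sp <- cell_spec("ON-transient",
                  rate_profile(10, on_amp = 200, on_latency = 80,
                               on_tau = 150),
                  n_blocks = 5, seed = 13)
  m <- response_metrics(simulate_spike_train(sp, ep), ep)
  expect_equal(m$A1tau2, 150, tolerance = 0.2)

  # matched ON-OFF lobes: amplitudes agree within sampling error
  # (relative SD of each smoothed peak ~ 1/sqrt(rate x window x blocks))
  spb <- cell_spec("ON-OFF",
                   rate_profile(10, on_amp = 200, on_latency = 80,
                                on_tau = 60, off_amp = 200,
                                off_latency = 80, off_tau = 60),
                   n_blocks = 20, seed = 17)
  mb <- response_metrics(simulate_spike_train(spb, ep), ep)
  expect_lt(abs(mb$A1 - mb$A2) / mean(c(mb$A1, mb$A2)), 0.4)
})
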