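make_size_series_trains <- function(seed = 5, n_blocks = 5,
                                    epoch = default_epoch()) {
  series <- stimulus_series("spot_size")
  tuning <- function(sz) exp(-((log(sz) - log(300)) / 0.9)^2 / 2)
  trains <- lapply(stats::setNames(series$levels, series$levels), function(sz) {
    prof <- rate_profile(10, on_amp = 150 * tuning(sz))
    simulate_spike_train(cell_spec("ON-transient", prof, n_blocks = n_blocks,
                                   seed = seed + round(sz)), epoch)
  })
  list(series = series, trains = trains)
}

test_that("analyze_series finds the preferred spot size", {
  ep <- default_epoch()
  fx <- make_size_series_trains()
  res <- analyze_series(fx$trains, fx$series, ep)
  expect_equal(res$preferred_level, 300)
  expect_equal(max(res$normalized_A), 1)
  expect_true(all(res$normalized_A >= 0 & res$normalized_A <= 1))
  # a missing level is recorded absent, not imputed
  partial <- fx$trains[-2]
  res2 <- analyze_series(partial, fx$series, ep)
  expect_false(res2$metrics$present[2])
  expect_true(is.na(res2$metrics$A1[2]))
})

test_that("normalize_amplitudes arithmetic, idempotence, tie rule", {
  mk <- function(A, levels = seq_along(A)) {
    structure(list(metrics = data.frame(level = levels, A1 = A),
                   normalized_A = NULL, preferred_level = NA, responsive = FALSE),
              class = "series_result")
  }
  r <- normalize_amplitudes(mk(c(10, 20, 40)))
  expect_equal(r$normalized_A, c(0.25, 0.5, 1))
  expect_equal(normalize_amplitudes(mk(rep(7, 4)))$normalized_A, rep(1, 4))
  expect_equal(normalize_amplitudes(mk(c(0, 5, 0)))$normalized_A, c(0, 1, 0))
  # ties broken towards the smaller level
  expect_equal(normalize_amplitudes(mk(c(3, 9, 9)))$preferred_level, 2)
  # idempotent
  expect_equal(normalize_amplitudes(r)$normalized_A, r$normalized_A)
  # all non-positive: flagged, no normalization
  r0 <- normalize_amplitudes(mk(c(-2, 0)))
  expect_false(r0$responsive)
  expect_true(all(is.na(r0$normalized_A)))
})

test_that("flicker_amplitude measures cycle modulation", {
  sp <- cell_spec("ON-transient", rate_profile(30, on_amp = 1e-9),
                  n_blocks = 5, seed = 3)
  # stationary train: amplitude near zero relative to a modulated one
  st <- simulate_flicker_train(sp, 2, depth = 0)
  a0 <- flicker_amplitude(st, 2)
  # fully modulated at 2 Hz: peak-trough of rate = 2 r0 m
  tr <- simulate_flicker_train(sp, 2, cutoff = 8, depth = 1)
  m <- attr(tr, "modulation_depth")
  a <- flicker_amplitude(tr, 2)
  expect_equal(a, 2 * 30 * m, tolerance = 0.15)
  expect_lt(a0, 0.35 * a)
  # the generator's low-pass law shows up in the measurements
  hi <- simulate_flicker_train(sp, 12, cutoff = 8, depth = 1)
  expect_lt(flicker_amplitude(hi, 12), a)
  # needs at least 5 complete cycles
  short <- spike_train(list(stats::runif(30, 0, 2)), 2)
  expect_error(flicker_amplitude(short, 1), "5 complete cycles")
})

test_that("compare_genotypes agrees with the aov oracle", {
  d <- simulate_series_metrics(n_cells = 8, seed = 5, level_effect = 30,
                               group_means = c(WT = 150, KO = 120))
  r <- compare_genotypes(d)
  da <- d
  da$cell <- factor(da$cell); da$group <- factor(da$group)
  da$level <- factor(da$level)
  a <- summary(stats::aov(value ~ group * level + Error(cell), data = da))
  atab1 <- a[["Error: cell"]][[1]]
  atab2 <- a[["Error: Within"]][[1]]
  expect_equal(r$group$F, atab1["group", "F value"], tolerance = 1e-8)
  expect_equal(r$group$p, atab1["group", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(r$level$F, atab2["level", "F value"], tolerance = 1e-8)
  expect_equal(r$group_by_level$F, atab2["group:level", "F value"],
               tolerance = 1e-8)
  expect_equal(r$group$df1, 1)
  expect_equal(r$group$df2, 14)
  expect_true(r$gg_epsilon > 1 / 5 && r$gg_epsilon <= 1)
})

test_that("compare_genotypes input contracts", {
  d <- simulate_series_metrics(n_cells = 3, seed = 2)
  # identical data in both groups: group F is exactly 0
  d2 <- d
  d2$value <- rep(d$value[d$group == "WT"], 2)
  expect_equal(compare_genotypes(d2)$group$F, 0, tolerance = 1e-20)
  # unbalanced level sets rejected with the offending cell named
  d3 <- d[-1, ]
  expect_error(compare_genotypes(d3), "c001")
})

test_that("compare_genotypes is calibrated and powered", {
  # type-I error at nominal 5% (400 null replicates here; the acceptance
  # suite runs the full 1000)
  ps <- vapply(1:400, function(i)
    compare_genotypes(simulate_series_metrics(n_cells = 15, seed = i))$group$p,
    numeric(1))
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.08)
  # 3x difference in the response-duration mean, n = 15/group
  pw <- vapply(1:100, function(i)
    compare_genotypes(simulate_series_metrics(
      n_cells = 15, group_means = c(WT = 180, KO = 60),
      seed = 5000 + i))$group$p, numeric(1))
  expect_gte(mean(pw < 0.05), 0.8)
})
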