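#' Specification of a synthetic single-flash ERG waveform
#'
#' The waveform is a negative Gaussian lobe (a-wave) followed by a positive
#' Gaussian lobe (b-wave) plus Gaussian noise. Lobe widths are Gaussian
#' standard deviations in ms.
#'
#' @param a_amp magnitude of the negative a-wave lobe, uV (>= 0)
#' @param a_latency time of the a-wave trough, ms after flash onset
#' @param b_amp magnitude of the positive b-wave lobe, uV (>= 0)
#' @param b_latency time of the b-wave peak, ms after flash onset
#' @param a_width,b_width lobe standard deviations, ms
#' @param noise_sd additive Gaussian noise, uV
#' @param sampling_rate Hz
#' @return object of class `erg_spec`
#' @export
erg_spec <- function(a_amp = 100, a_latency = 15, b_amp = 300, b_latency = 60,
                     a_width = 8, b_width = 12, noise_sd = 0,
                     sampling_rate = 1000) {
  stopifnot(a_amp >= 0, b_amp >= 0, sampling_rate > 0, noise_sd >= 0)
  if (a_latency >= b_latency) stop("a_latency must precede b_latency")
  structure(list(a_amp = a_amp, a_latency = a_latency, b_amp = b_amp,
                 b_latency = b_latency, a_width = a_width, b_width = b_width,
                 noise_sd = noise_sd, sampling_rate = sampling_rate),
            class = "erg_spec")
}

#' Flash-aligned ERG trace container
#'
#' @param time_ms time in ms relative to flash onset (uniformly sampled,
#'   including at least 20 ms pre-flash)
#' @param voltage uV
#' @param intensity flash intensity, log cd*s/m^2
#' @param adaptation `"scotopic"` or `"photopic"`
#' @return object of class `erg_trace`
#' @export
erg_trace <- function(time_ms, voltage, intensity = NA_real_,
                      adaptation = c("scotopic", "photopic")) {
  adaptation <- match.arg(adaptation)
  stopifnot(length(time_ms) == length(voltage))
  dt <- diff(time_ms)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("erg_trace requires uniform sampling")
  structure(list(time_ms = as.numeric(time_ms), voltage = as.numeric(voltage),
                 intensity = intensity, adaptation = adaptation),
            class = "erg_trace")
}

#' Simulate a single-flash ERG trace
#'
#' The returned trace is the average of `n_sweeps` repeated flash
#' presentations, each carrying independent noise of SD `noise_sd` --
#' flash ERGs are routinely recorded as small sweep averages, so the
#' effective trace noise is `noise_sd / sqrt(n_sweeps)`.
#'
#' @param spec an [erg_spec()]
#' @param t_range ms range relative to flash onset (default -50 to 300)
#' @param seed seed for the noise
#' @param n_sweeps flash repetitions averaged into the trace (default 4)
#' @param intensity,adaptation stored as metadata on the trace
#' @return an `erg_trace` with attribute `ground_truth` (the spec)
#' @export
simulate_erg <- function(spec, t_range = c(-50, 300), seed = 1L,
                         n_sweeps = 4,
                         intensity = NA_real_, adaptation = "scotopic") {
  stopifnot(inherits(spec, "erg_spec"), n_sweeps >= 1)
  dt <- 1000 / spec$sampling_rate
  t <- seq(t_range[1], t_range[2], by = dt)
  v <- -spec$a_amp * exp(-((t - spec$a_latency) / spec$a_width)^2 / 2) +
        spec$b_amp * exp(-((t - spec$b_latency) / spec$b_width)^2 / 2)
  # lobes belong to the response, not the pre-flash baseline
  v[t < 0] <- 0
  if (spec$noise_sd > 0) {
    old <- .Random.seed_store()
    set.seed(split_seed(seed, 17))
    noise <- rowMeans(matrix(stats::rnorm(length(v) * n_sweeps, 0,
                                          spec$noise_sd),
                             ncol = n_sweeps))
    v <- v + noise
    .Random.seed_restore(old)
  }
  out <- erg_trace(t, v, intensity = intensity, adaptation = adaptation)
  attr(out, "ground_truth") <- spec
  out
}

#' Simulate a flicker-ERG frequency series
#'
#' Each frequency yields one trace: a pre-stimulus baseline segment followed
#' by a sinusoidal steady-state response whose trough-to-peak amplitude
#' follows a first-order low-pass law
#' `A(f) = amp0 / sqrt(1 + (f / cutoff)^2)`, plus Gaussian noise. Emulates
#' the progressive amplitude decline towards flicker fusion.
#'
#' @param frequencies Hz, strictly increasing (default: the standard
#'   12-step flicker protocol 0.5-30 Hz)
#' @param amp0 trough-to-peak amplitude at DC, uV
#' @param cutoff low-pass cutoff, Hz
#' @param noise_sd additive noise, uV
#' @param duration stimulation seconds per frequency
#' @param pre_stim pre-stimulus baseline seconds
#' @param sampling_rate Hz
#' @param seed seed
#' @return list with `frequencies`, `traces` (list of `erg_trace`, flash/train
#'   onset at t = 0) and `ground_truth` (amplitude per frequency)
#' @export
simulate_erg_flicker <- function(frequencies = c(0.5, 1, 2, 3, 5, 7, 10, 12,
                                                 15, 18, 20, 30),
                                 amp0 = 200, cutoff = 2, noise_sd = 5,
                                 duration = 8, pre_stim = 0.2,
                                 sampling_rate = 1000, seed = 1L) {
  stopifnot(all(diff(frequencies) > 0), amp0 >= 0, cutoff > 0)
  amps <- amp0 / sqrt(1 + (frequencies / cutoff)^2)
  traces <- vector("list", length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    dt <- 1000 / sampling_rate
    t <- seq(-pre_stim * 1000, duration * 1000, by = dt)
    v <- ifelse(t >= 0, amps[i] / 2 * sin(2 * pi * f * t / 1000), 0)
    if (noise_sd > 0) {
      old <- .Random.seed_store()
      set.seed(split_seed(seed, 23, i))
      v <- v + stats::rnorm(length(v), 0, noise_sd)
      .Random.seed_restore(old)
    }
    traces[[i]] <- erg_trace(t, v)
  }
  list(frequencies = frequencies, traces = traces,
       ground_truth = stats::setNames(amps, frequencies))
}
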