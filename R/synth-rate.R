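#' Firing-rate profile of a synthetic ganglion cell
#'
#' The instantaneous firing rate is a constant baseline plus up to two
#' response lobes: an ON lobe referenced to stimulus onset and an OFF lobe
#' referenced to stimulus offset. Each lobe rises linearly over `rise_time`
#' to its amplitude at its latency and then decays exponentially with its
#' decay constant, so that the extracted response-duration parameter (time
#' from the peak to the amplitude/e crossing) has the closed form `tau`.
#'
#' @param baseline_rate spontaneous firing rate in Hz (>= 0)
#' @param on_amp,on_latency,on_tau ON lobe amplitude (Hz), latency to peak
#'   (ms after onset) and exponential decay constant (ms)
#' @param off_amp,off_latency,off_tau OFF lobe parameters, referenced to
#'   stimulus offset
#' @param rise_time ms taken by the linear leading edge of each lobe
#' @return an object of class `rate_profile`
#' @export
rate_profile <- function(baseline_rate = 10,
                         on_amp = 0, on_latency = 80, on_tau = 60,
                         off_amp = 0, off_latency = 80, off_tau = 60,
                         rise_time = 10) {
  stopifnot(baseline_rate >= 0, on_amp >= 0, off_amp >= 0,
            on_tau > 0, off_tau > 0, rise_time > 0)
  structure(list(baseline_rate = baseline_rate,
                 on_lobe = c(amp = on_amp, latency = on_latency, tau = on_tau),
                 off_lobe = c(amp = off_amp, latency = off_latency, tau = off_tau),
                 rise_time = rise_time),
            class = "rate_profile")
}

# One lobe's contribution at s ms after its reference event (vectorized).
lobe_rate <- function(s, amp, latency, tau, rise_time) {
  if (amp <= 0) return(numeric(length(s)))
  r <- numeric(length(s))
  rising <- s >= (latency - rise_time) & s <= latency
  r[rising] <- amp * (s[rising] - (latency - rise_time)) / rise_time
  decaying <- s > latency
  r[decaying] <- amp * exp(-(s[decaying] - latency) / tau)
  r
}

#' Evaluate a rate profile at given times
#'
#' @param profile a [rate_profile()]
#' @param t_ms times in ms from block start (vectorized)
#' @param epoch a [stimulus_epoch()] giving onset/offset
#' @return firing rate in Hz at each time (clamped at 0)
#' @export
evaluate_rate <- function(profile, t_ms, epoch) {
  stopifnot(inherits(profile, "rate_profile"), inherits(epoch, "stimulus_epoch"))
  on <- profile$on_lobe; off <- profile$off_lobe
  r <- profile$baseline_rate +
    lobe_rate(t_ms - epoch$onset * 1000, on["amp"], on["latency"], on["tau"],
              profile$rise_time) +
    lobe_rate(t_ms - epoch$offset * 1000, off["amp"], off["latency"], off["tau"],
              profile$rise_time)
  pmax(r, 0)
}

#' Specification of one synthetic ganglion cell
#'
#' @param true_class one of `"ON-transient"`, `"ON-sustained"`, `"OFF"`,
#'   `"ON-OFF"`; must be consistent with the lobe amplitudes (an OFF cell
#'   has zero ON amplitude, and vice versa)
#' @param profile a [rate_profile()]
#' @param n_blocks repeated stimulus blocks to simulate
#' @param seed random seed for this cell
#' @return an object of class `cell_spec`
#' @export
cell_spec <- function(true_class = c("ON-transient", "ON-sustained", "OFF", "ON-OFF"),
                      profile, n_blocks = 5, seed = 1L) {
  true_class <- match.arg(true_class)
  stopifnot(inherits(profile, "rate_profile"), n_blocks >= 1)
  on_amp <- profile$on_lobe["amp"]; off_amp <- profile$off_lobe["amp"]
  ok <- switch(true_class,
    "OFF"    = on_amp == 0 && off_amp > 0,
    "ON-OFF" = on_amp > 0 && off_amp > 0,
    on_amp > 0 && off_amp == 0)
  if (!ok) stop("lobe amplitudes inconsistent with true_class '", true_class, "'")
  structure(list(true_class = true_class, profile = profile,
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
            class = "cell_spec")
}

# Deterministic seed splitting: one top-level seed fans out to independent
# per-cell / per-block substreams. Kept below 2^31 for R's 32-bit seeds.
split_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}
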