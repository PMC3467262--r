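# Shared fixtures; everything is generated in code, no stored data.

default_epoch <- function(...) stimulus_epoch(...)

# noise-free PSTH evaluated from a rate profile on a 1 ms grid
analytic_psth <- function(profile, epoch, bin_width_ms = 1) {
  t <- seq(bin_width_ms / 2, epoch$block_duration * 1000 - bin_width_ms / 2,
           by = bin_width_ms)
  psth_from_rates(evaluate_rate(profile, t, epoch), bin_width_ms)
}

# detection fixture: ~20 Hz spikes with a 2.5 ms dead time (a physiological
# refractory period; without it sub-millisecond ISIs are unresolvable for
# any threshold detector) over a 10 s trace
make_detection_fixture <- function(seed = 99, amp_sigma = 5, noise_sd = 10,
                                   duration = 10) {
  set.seed(seed)
  t <- cumsum(stats::rexp(40 * duration, 20) + 0.0025)
  t <- t[t < duration - 0.01]
  train <- spike_train(list(t), duration)
  simulate_raw_trace(train, waveform_amp = amp_sigma * noise_sd,
                     noise_sd = noise_sd, seed = seed + 1)
}
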