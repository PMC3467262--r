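#' Biphasic extracellular spike template
#'
#' A derivative-of-Gaussian waveform with a dominant negative phase, the
#' classic extracellular action-potential shape. Scaled so the negative
#' extremum equals `-amp`.
#'
#' @param amp peak (negative-phase) amplitude in uV
#' @param width_ms total waveform support in ms (default 1.6)
#' @param sampling_rate Hz
#' @return numeric vector of template samples
#' @export
spike_template <- function(amp, width_ms = 1.6, sampling_rate = 20000) {
  n <- max(3L, round(width_ms / 1000 * sampling_rate))
  t <- seq(-1, 1, length.out = n)
  w <- -t * exp(-(t / 0.35)^2 / 2)      # biphasic, negative phase first-dominant
  w / max(abs(w)) * -sign(min(w)) * amp # negative extremum = -amp
}

#' Raw extracellular trace container
#'
#' @param samples voltage samples in uV
#' @param sampling_rate Hz
#' @param start_time seconds (trace time origin)
#' @return object of class `raw_trace`
#' @export
raw_trace <- function(samples, sampling_rate = 20000, start_time = 0) {
  stopifnot(sampling_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, start_time = start_time),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Simulate a raw extracellular trace from a spike train
#'
#' Gaussian background noise plus a biphasic spike template inserted at each
#' spike timestamp. Blocks are concatenated; ground-truth spike times (in
#' concatenated trace time) are retained for detection scoring.
#'
#' @param train a [spike_train()]
#' @param waveform_amp template peak amplitude in uV (> 0)
#' @param noise_sd noise standard deviation in uV (>= 0)
#' @param sampling_rate Hz, default 20000
#' @param seed seed for the noise
#' @return a `raw_trace` with attribute `true_times` (seconds)
#' @export
simulate_raw_trace <- function(train, waveform_amp, noise_sd = 1,
                               sampling_rate = 20000, seed = 1L) {
  stopifnot(inherits(train, "spike_train"))
  if (waveform_amp <= 0) stop("waveform_amp must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nblk <- train$n_blocks
  n_per_block <- round(train$block_duration * sampling_rate)
  n <- n_per_block * nblk
  old <- .Random.seed_store()
  set.seed(split_seed(seed, 7))
  samples <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  .Random.seed_restore(old)
  tmpl <- spike_template(waveform_amp, sampling_rate = sampling_rate)
  half <- which.min(tmpl) - 1L   # negative extremum lands on the spike sample
  true_times <- numeric(0)
  for (b in seq_len(nblk)) {
    ts <- train$blocks[[b]] + (b - 1) * train$block_duration
    for (tt in ts) {
      # template centre at the spike's negative extremum sample
      centre <- round(tt * sampling_rate) + 1L
      idx <- (centre - half):(centre - half + length(tmpl) - 1L)
      ok <- idx >= 1L & idx <= n
      samples[idx[ok]] <- samples[idx[ok]] + tmpl[ok]
    }
    true_times <- c(true_times, ts)
  }
  out <- raw_trace(samples, sampling_rate)
  attr(out, "true_times") <- true_times
  out
}
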