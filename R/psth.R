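#' Build a peri-stimulus time histogram
#'
#' Spike counts are pooled across the repeated stimulus blocks and converted
#' to rate: `rate = count / (n_blocks * bin_width)`. With the default 1 ms
#' bins the unsmoothed PSTH exactly conserves spike counts
#' (`rate * bin_width * n_blocks` is an integer per bin).
#'
#' @param train a [spike_train()] aligned to block start
#' @param epoch a [stimulus_epoch()] (provides the alignment metadata)
#' @param bin_width_ms bin width in ms (default 1)
#' @return object of class `psth`: `rates` (Hz per bin), `t_ms` (bin
#'   centres, ms from block start), `bin_width_ms`, `n_blocks`,
#'   `smoothing_sigma` (`NA` until smoothed)
#' @export
build_psth <- function(train, epoch, bin_width_ms = 1) {
  stopifnot(inherits(train, "spike_train"), inherits(epoch, "stimulus_epoch"))
  stopifnot(bin_width_ms > 0)
  dur_ms <- train$block_duration * 1000
  breaks <- seq(0, dur_ms, by = bin_width_ms)
  if (breaks[length(breaks)] < dur_ms) breaks <- c(breaks, dur_ms)
  all_spikes <- unlist(train$blocks) * 1000
  if (!length(all_spikes))
    warning("no spikes in any block; PSTH is all zero")
  counts <- if (length(all_spikes))
    graphics::hist(all_spikes, breaks = breaks, plot = FALSE,
                   right = FALSE)$counts
  else numeric(length(breaks) - 1)
  rates <- counts / (train$n_blocks * bin_width_ms / 1000)
  structure(list(rates = rates,
                 t_ms = (breaks[-length(breaks)] + breaks[-1]) / 2,
                 bin_width_ms = bin_width_ms,
                 n_blocks = train$n_blocks,
                 smoothing_sigma = NA_real_),
            class = "psth")
}

#' Construct a PSTH directly from rate values
#'
#' Useful for noise-free analytic checks: evaluates a known rate function on
#' a regular grid and wraps it as a `psth`.
#'
#' @param rates Hz per bin
#' @param bin_width_ms bin width, ms
#' @param t0_ms time of the first bin centre (default `bin_width_ms / 2`)
#' @param n_blocks metadata only
#' @return a `psth`
#' @export
psth_from_rates <- function(rates, bin_width_ms = 1, t0_ms = bin_width_ms / 2,
                            n_blocks = 1) {
  structure(list(rates = as.numeric(rates),
                 t_ms = t0_ms + (seq_along(rates) - 1) * bin_width_ms,
                 bin_width_ms = bin_width_ms, n_blocks = n_blocks,
                 smoothing_sigma = NA_real_),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins x %g ms, %d block(s)%s\n",
              length(x$rates), x$bin_width_ms, x$n_blocks,
              if (is.na(x$smoothing_sigma)) ""
              else sprintf(", smoothed (sigma %g ms)", x$smoothing_sigma)))
  invisible(x)
}

#' Smooth a PSTH with a Gaussian kernel
#'
#' Convolution with a Gaussian of standard deviation `sigma_ms` (default
#' 25 ms, the conventional smoothing for ganglion-cell PSTHs), truncated at
#' four sigma and renormalized. Boundaries are handled by reflection
#' padding, which preserves total rate mass away from strong edge
#' gradients.
#'
#' @param psth a [build_psth()] result
#' @param sigma_ms kernel standard deviation in ms
#' @return a smoothed `psth`
#' @export
smooth_psth <- function(psth, sigma_ms = 25) {
  stopifnot(inherits(psth, "psth"))
  if (sigma_ms <= 0) stop("smoothing sigma must be positive")
  r <- psth$rates
  sig_bins <- sigma_ms / psth$bin_width_ms
  half <- max(1L, ceiling(4 * sig_bins))
  kern <- stats::dnorm(seq(-half, half), sd = sig_bins)
  kern <- kern / sum(kern)
  n <- length(r)
  pad <- min(half, n - 1L)
  xp <- c(rev(r[seq_len(pad) + 1L]), r, rev(r[n - seq_len(pad)]))
  sm <- stats::filter(xp, kern, method = "convolution", sides = 2)
  out <- psth
  out$rates <- as.numeric(sm[(pad + 1):(pad + n)])
  out$smoothing_sigma <- sigma_ms
  out
}

#' Baseline firing rate before stimulus onset
#'
#' Mean PSTH rate over the `window_ms` (default 100 ms) immediately
#' preceding stimulus onset.
#'
#' @param psth a `psth`
#' @param epoch a [stimulus_epoch()]
#' @param window_ms baseline window length, ms
#' @return baseline rate in Hz
#' @export
estimate_baseline <- function(psth, epoch, window_ms = 100) {
  stopifnot(inherits(psth, "psth"), inherits(epoch, "stimulus_epoch"))
  onset_ms <- epoch$onset * 1000
  if (onset_ms - psth$t_ms[1] + psth$bin_width_ms / 2 < window_ms)
    stop(sprintf("need >= %g ms of pre-onset data for the baseline window",
                 window_ms))
  sel <- psth$t_ms >= (onset_ms - window_ms) & psth$t_ms < onset_ms
  mean(psth$rates[sel])
}
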