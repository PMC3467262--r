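# Shared peak + decay extraction on a baseline-corrected PSTH. `ref_ms` is
# the event the latency is referenced to (stimulus onset for ON metrics,
# offset for OFF); the peak is searched in [win_start, win_end] and the
# amplitude/e crossing anywhere after the peak up to the end of the PSTH.
extract_lobe_metrics <- function(psth, baseline, ref_ms, win_start, win_end,
                                 response_threshold) {
  corr <- psth$rates - baseline
  t <- psth$t_ms
  sel <- which(t >= win_start & t <= win_end)
  if (!length(sel)) stop("search window outside the PSTH")
  ipk <- sel[which.max(corr[sel])]
  A <- corr[ipk]
  L <- t[ipk] - ref_ms
  crit <- A / exp(1)
  tau <- NA_real_
  censored <- FALSE
  if (A > response_threshold) {
    after <- which(t > t[ipk])
    below <- after[corr[after] < crit]
    if (length(below)) {
      j <- below[1]
      # linear interpolation between the last bin above and first below
      t_cross <- if (j > 1 && corr[j - 1] >= crit)
        t[j - 1] + (corr[j - 1] - crit) / (corr[j - 1] - corr[j]) *
          (t[j] - t[j - 1])
      else t[j]
      tau <- t_cross - t[ipk]
    } else censored <- TRUE
  }
  responsive <- A > response_threshold
  list(amplitude = A, latency = L, tau = tau,
       censored = censored, responsive = responsive)
}

# Non-response criterion: amplitude below twice the standard error of the
# baseline-window bins. Bin correlation after smoothing makes this
# conservative for flat cells, which is the intended direction.
baseline_se <- function(psth, epoch, window_ms = 100) {
  onset_ms <- epoch$onset * 1000
  sel <- psth$t_ms >= (onset_ms - window_ms) & psth$t_ms < onset_ms
  r <- psth$rates[sel]
  if (length(r) < 2) return(0)
  stats::sd(r) / sqrt(length(r))
}

#' Extract ON response metrics (A1, L1, A1tau2)
#'
#' `A1` is the baseline-corrected peak rate after stimulus onset, `L1` the
#' time from onset to that peak, and `A1tau2` the response duration: the
#' time from the peak to the first subsequent crossing below `A1/e`
#' (linear interpolation between bins). If no crossing occurs before the
#' end of the PSTH the duration is censored.
#'
#' @param psth a (typically smoothed) [build_psth()] result
#' @param baseline baseline rate in Hz, see [estimate_baseline()]
#' @param epoch a [stimulus_epoch()]
#' @param window_ms ON search window, ms after onset; default
#'   `c(0, offset - onset)` -- the ON peak is searched during the stimulus
#'   only, so the rising edge of an early OFF lobe (spread backwards in
#'   time by the smoothing kernel) cannot masquerade as an ON response
#' @param response_threshold Hz; amplitudes at or below it are flagged
#'   non-responsive. Default `2 * baseline_se(psth, epoch)`
#' @return list with `A1` (Hz), `L1` (ms), `A1tau2` (ms or `NA`),
#'   `censored`, `responsive`
#' @export
extract_on_metrics <- function(psth, baseline, epoch,
                               window_ms = NULL, response_threshold = NULL) {
  stopifnot(inherits(psth, "psth"), inherits(epoch, "stimulus_epoch"))
  onset_ms <- epoch$onset * 1000
  if (is.null(window_ms))
    window_ms <- c(0, (epoch$offset - epoch$onset) * 1000)
  if (is.null(response_threshold))
    response_threshold <- 2 * baseline_se(psth, epoch)
  m <- extract_lobe_metrics(psth, baseline, onset_ms,
                            onset_ms + window_ms[1], onset_ms + window_ms[2],
                            response_threshold)
  list(A1 = m$amplitude, L1 = m$latency, A1tau2 = m$tau,
       censored = m$censored, responsive = m$responsive)
}

#' Extract OFF response metrics (A2, L2, A2tau2)
#'
#' As [extract_on_metrics()] with the search window anchored at stimulus
#' offset. The default window mirrors the ON window (stimulus duration plus
#' 50 ms, truncated at the block end): with asymmetric windows the extreme
#' value of the smoothed noise over the longer window would bias the bias
#' index of every cell towards OFF.
#'
#' @inheritParams extract_on_metrics
#' @param window_ms ms after offset; default
#'   `c(0, min(offset - onset + 50 ms, block_end - offset))`
#' @return list with `A2`, `L2`, `A2tau2`, `censored`, `responsive`
#' @export
extract_off_metrics <- function(psth, baseline, epoch,
                                window_ms = NULL, response_threshold = NULL) {
  stopifnot(inherits(psth, "psth"), inherits(epoch, "stimulus_epoch"))
  offset_ms <- epoch$offset * 1000
  if (is.null(window_ms))
    window_ms <- c(0, min((epoch$offset - epoch$onset) * 1000 + 50,
                          max(psth$t_ms) - offset_ms))
  if (is.null(response_threshold))
    response_threshold <- 2 * baseline_se(psth, epoch)
  m <- extract_lobe_metrics(psth, baseline, offset_ms,
                            offset_ms + window_ms[1], offset_ms + window_ms[2],
                            response_threshold)
  list(A2 = m$amplitude, L2 = m$latency, A2tau2 = m$tau,
       censored = m$censored, responsive = m$responsive)
}

#' Full response parameterization of one cell
#'
#' Convenience wrapper: PSTH construction, smoothing, baseline estimation
#' and ON + OFF metric extraction in one call.
#'
#' @param train a [spike_train()]
#' @param epoch a [stimulus_epoch()]
#' @param bin_width_ms PSTH bin width (default 1 ms)
#' @param sigma_ms Gaussian smoothing sigma (default 25 ms)
#' @return list with `baseline` plus the fields of [extract_on_metrics()]
#'   and [extract_off_metrics()]
#' @export
response_metrics <- function(train, epoch, bin_width_ms = 1, sigma_ms = 25) {
  p <- suppressWarnings(build_psth(train, epoch, bin_width_ms))
  ps <- smooth_psth(p, sigma_ms)
  b <- estimate_baseline(ps, epoch)
  on <- extract_on_metrics(ps, b, epoch)
  off <- extract_off_metrics(ps, b, epoch)
  c(list(baseline = b), on, off[c("A2", "L2", "A2tau2")],
    list(off_censored = off$censored, off_responsive = off$responsive))
}
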