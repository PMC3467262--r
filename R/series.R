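#' Analyze one cell across a stimulus series
#'
#' Extracts response metrics at every series level, normalizes the ON
#' amplitudes to the per-cell maximum, and reports the preferred level
#' (the level maximizing A1; ties broken towards the smaller level).
#'
#' @param trains named list of [spike_train()]s, one per level, names
#'   matching `series$levels`; missing levels are recorded as absent
#' @param series a [stimulus_series()]
#' @param epoch a [stimulus_epoch()] shared by all levels
#' @param ... passed to [response_metrics()]
#' @return object of class `series_result`: data frame `metrics` (one row
#'   per level), `normalized_A`, `preferred_level` (`NA` if the cell never
#'   responds), `responsive`
#' @export
analyze_series <- function(trains, series, epoch, ...) {
  stopifnot(inherits(series, "stimulus_series"))
  levels <- series$levels
  rows <- lapply(levels, function(lv) {
    tr <- trains[[as.character(lv)]]
    if (is.null(tr))
      return(data.frame(level = lv, present = FALSE, baseline = NA, A1 = NA,
                        L1 = NA, A1tau2 = NA, A2 = NA, L2 = NA, A2tau2 = NA))
    m <- response_metrics(tr, epoch, ...)
    data.frame(level = lv, present = TRUE, baseline = m$baseline,
               A1 = m$A1, L1 = m$L1, A1tau2 = ifelse(is.null(m$A1tau2), NA, m$A1tau2),
               A2 = m$A2, L2 = m$L2, A2tau2 = ifelse(is.null(m$A2tau2), NA, m$A2tau2))
  })
  metrics <- do.call(rbind, rows)
  res <- structure(list(metrics = metrics, series = series,
                        normalized_A = NULL, preferred_level = NA_real_,
                        responsive = FALSE),
                   class = "series_result")
  normalize_amplitudes(res)
}

#' Normalize series amplitudes to the per-cell maximum
#'
#' Divides each level's A1 by the maximum over levels, giving values in
#' `[0, 1]` with 1 at the preferred level. Idempotent. Cells whose
#' amplitudes are all non-positive are flagged non-responsive and left
#' unnormalized.
#'
#' @param result a `series_result`
#' @return the `series_result` with `normalized_A` and `preferred_level`
#' @export
normalize_amplitudes <- function(result) {
  stopifnot(inherits(result, "series_result"))
  A <- result$metrics$A1
  ok <- !is.na(A)
  if (!any(ok) || max(A[ok]) <= 0) {
    result$responsive <- FALSE
    result$normalized_A <- rep(NA_real_, length(A))
    result$preferred_level <- NA_real_
    return(result)
  }
  amax <- max(A[ok])
  result$normalized_A <- pmax(A, 0) / amax
  # argmax with ties broken towards the smaller stimulus level
  result$preferred_level <- result$metrics$level[ok][which.max(A[ok])]
  result$responsive <- TRUE
  result
}

#' Flicker response amplitude from a cycle-averaged histogram
#'
#' Folds the spike train over the stimulus period, builds a cycle
#' histogram, smooths it circularly, and reports the amplitude as cycle
#' peak minus cycle minimum -- the closest analogue of a baseline-corrected
#' peak when no pre-stimulus window exists within the cycle.
#'
#' @param train a [spike_train()] of flicker blocks
#' @param frequency stimulus frequency, Hz
#' @param n_bins bins per cycle (default 50)
#' @param sigma_frac circular smoothing sigma as a fraction of the period
#'   (default 0.05)
#' @param mode `"folded"` (cycle-averaged, default) or `"first_cycle"`
#' @return amplitude in Hz
#' @export
flicker_amplitude <- function(train, frequency, n_bins = 50,
                              sigma_frac = 0.05,
                              mode = c("folded", "first_cycle")) {
  stopifnot(inherits(train, "spike_train"), frequency > 0)
  mode <- match.arg(mode)
  period <- 1 / frequency
  n_cycles <- floor(train$block_duration / period)
  if (n_cycles < 5) stop("need at least 5 complete cycles per block")
  span <- n_cycles * period
  phases <- unlist(lapply(train$blocks, function(b) {
    b <- b[b < span]
    if (mode == "first_cycle") b <- b[b < period]
    b %% period
  }))
  denom_cycles <- if (mode == "first_cycle") 1 else n_cycles
  bw <- period / n_bins
  counts <- graphics::hist(phases, breaks = seq(0, period, length.out = n_bins + 1),
                           plot = FALSE, right = FALSE)$counts
  rates <- counts / (train$n_blocks * denom_cycles * bw)
  # circular Gaussian smoothing
  sig <- sigma_frac * n_bins
  half <- ceiling(4 * sig)
  kern <- stats::dnorm(seq(-half, half), sd = sig)
  kern <- kern / sum(kern)
  ext <- c(rates[(n_bins - half + 1):n_bins], rates, rates[1:half])
  sm <- as.numeric(stats::filter(ext, kern, sides = 2))[(half + 1):(half + n_bins)]
  max(sm) - min(sm)
}
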