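#' Default synthetic ganglion-cell population
#'
#' The standard 60-cell test fixture: 20 ON-transient, 20 ON-OFF and 20 OFF
#' cells with well-separated lobe parameters, baseline rates drawn from
#' 5-20 Hz, and deterministic per-cell seeds split from one top-level seed.
#'
#' Lobe amplitudes are 150-250 Hz, the order of magnitude of transient
#' ganglion-cell PSTH peaks: "well separated" has to be read against the
#' 25 ms Gaussian smoothing (which attenuates a sharp exponential lobe by
#' roughly half) and against the Poisson noise of the smoothed peak
#' estimate, whose relative SD scales as one over the square root of the
#' spike count inside the smoothing window across the 5 blocks.
#' ON-transient cells decay with tau 40-70 ms (ground-truth response
#' duration well below the 200 ms transient/sustained boundary); ON-OFF
#' cells carry matched ON and OFF lobes; OFF cells only an OFF lobe.
#'
#' @param seed top-level seed
#' @param n_per_class cells per class (default 20)
#' @param n_blocks repeated blocks per cell (default 5)
#' @return named list of [cell_spec()]s; names are cell ids encoding the
#'   true class
#' @export
default_population <- function(seed = 1L, n_per_class = 20, n_blocks = 5) {
  old <- .Random.seed_store()
  set.seed(split_seed(seed, 97))
  specs <- list()
  make <- function(class, i) {
    base <- stats::runif(1, 5, 20)
    prof <- switch(class,
      "ON-transient" = rate_profile(base, on_amp = stats::runif(1, 150, 250),
                                    on_latency = stats::runif(1, 60, 100),
                                    on_tau = stats::runif(1, 40, 70)),
      "ON-OFF" = {
        # fully matched lobes: equal amplitude, latency and decay, so the
        # ON/OFF balance is symmetric by construction
        a <- stats::runif(1, 150, 250)
        lat <- stats::runif(1, 60, 100)
        tau <- stats::runif(1, 40, 70)
        rate_profile(base, on_amp = a, on_latency = lat, on_tau = tau,
                     off_amp = a, off_latency = lat, off_tau = tau)
      },
      "OFF" = rate_profile(base, off_amp = stats::runif(1, 150, 250),
                           off_latency = stats::runif(1, 60, 100),
                           off_tau = stats::runif(1, 40, 70)))
    cell_spec(class, prof, n_blocks = n_blocks,
              seed = split_seed(seed, match(class, c("ON-transient", "ON-OFF",
                                                     "OFF")), i))
  }
  for (class in c("ON-transient", "ON-OFF", "OFF")) {
    for (i in seq_len(n_per_class)) {
      id <- sprintf("%s_%02d", gsub("-", "", tolower(class)), i)
      specs[[id]] <- make(class, i)
    }
  }
  .Random.seed_restore(old)
  specs
}

#' Simulate and classify a cell population
#'
#' Runs the full chain for each cell: spike simulation, PSTH, smoothing,
#' baseline correction, ON/OFF metric extraction, bias index and
#' classification.
#'
#' @param specs named list of [cell_spec()]s, e.g. [default_population()]
#' @param epoch a [stimulus_epoch()]
#' @param ... classification options passed to [classify_cells()]
#' @return data frame: one row per cell with the true class, metrics, BI
#'   and assigned labels
#' @export
classify_population <- function(specs, epoch = stimulus_epoch(), ...) {
  rows <- lapply(names(specs), function(id) {
    sp <- specs[[id]]
    train <- simulate_spike_train(sp, epoch)
    m <- response_metrics(train, epoch)
    data.frame(cell = id, true_class = sp$true_class, baseline = m$baseline,
               A1 = m$A1, L1 = m$L1,
               A1tau2 = ifelse(is.na(m$A1tau2), NA_real_, m$A1tau2),
               A2 = m$A2, L2 = m$L2,
               A2tau2 = ifelse(is.na(m$A2tau2), NA_real_, m$A2tau2))
  })
  metrics <- do.call(rbind, rows)
  cls <- classify_cells(metrics, ...)
  merged <- merge(metrics, cls, by = "cell", sort = FALSE)
  # label in the population's own vocabulary for direct accuracy checks
  merged$predicted_class <- ifelse(
    merged$polarity == "ON",
    paste0("ON-", merged$kinetics),
    merged$polarity)
  merged
}
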