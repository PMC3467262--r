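#' Simulate spike trains for one cell by Poisson thinning
#'
#' Realizes an inhomogeneous Poisson process for each stimulus block by
#' thinning a homogeneous process against the profile maximum (evaluated on
#' a 1 ms grid). Identical `spec` (including its seed) always yields
#' bit-identical timestamps; each block uses its own deterministic
#' sub-seed so blocks are independent but reproducible.
#'
#' @param spec a [cell_spec()]
#' @param epoch a [stimulus_epoch()]; the block must include at least 100 ms
#'   of pre-onset baseline so the PSTH baseline window exists
#' @return object of class `spike_train`: a list with `blocks` (list of
#'   numeric timestamp vectors, seconds from block start), `n_blocks`,
#'   `block_duration`
#' @export
simulate_spike_train <- function(spec, epoch) {
  stopifnot(inherits(spec, "cell_spec"), inherits(epoch, "stimulus_epoch"))
  if (epoch$onset < 0.1)
    stop("block must include >= 100 ms of pre-onset baseline")
  dur_ms <- epoch$block_duration * 1000
  grid <- seq(0, dur_ms, by = 1)
  rmax <- max(evaluate_rate(spec$profile, grid, epoch))
  blocks <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    blocks[[b]] <- if (rmax <= 0) numeric(0) else {
      withr_seed <- split_seed(spec$seed, b)
      old <- .Random.seed_store()
      set.seed(withr_seed)
      n <- stats::rpois(1, rmax * epoch$block_duration)
      cand <- sort(stats::runif(n, 0, epoch$block_duration))
      keep <- stats::runif(n) < evaluate_rate(spec$profile, cand * 1000, epoch) / rmax
      .Random.seed_restore(old)
      cand[keep]
    }
  }
  spike_train(blocks, epoch$block_duration)
}

# Save/restore .Random.seed so simulators do not perturb the caller's RNG
# stream beyond their own deterministic substreams.
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' Construct a spike train container
#'
#' @param blocks list of numeric vectors of spike timestamps (seconds from
#'   block start), one per repeated stimulus block
#' @param block_duration block length in seconds
#' @return object of class `spike_train`
#' @export
spike_train <- function(blocks, block_duration) {
  if (!is.list(blocks)) blocks <- list(blocks)
  lapply(blocks, function(b) {
    if (length(b) && (any(b < 0) || any(b > block_duration)))
      stop("timestamps outside [0, block_duration]")
  })
  structure(list(blocks = lapply(blocks, as.numeric),
                 n_blocks = length(blocks),
                 block_duration = block_duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d block(s) x %.1f s, %d spikes total\n",
              x$n_blocks, x$block_duration, sum(lengths(x$blocks))))
  invisible(x)
}

#' Simulate a sinusoidally modulated (flicker-driven) spike train
#'
#' The rate is `r0 * (1 + m(f) sin(2 pi f t))` where the modulation depth
#' follows a first-order low-pass law `m(f) = depth / sqrt(1 + (f/cutoff)^2)`,
#' emulating the attenuation of ganglion-cell flicker responses at high
#' stimulus frequencies. Blocks are 10 s by default, matching the flicker
#' protocol. Ground-truth depth is stored in the result.
#'
#' @param spec a [cell_spec()]; its baseline_rate is the mean rate `r0`
#' @param frequency flicker frequency in Hz (> 0)
#' @param cutoff low-pass cutoff frequency in Hz
#' @param depth modulation depth at DC, in `[0, 1]`
#' @param block_duration seconds per flicker block (default 10)
#' @return a `spike_train` with attributes `modulation_depth` (effective
#'   depth at `frequency`) and `frequency`
#' @export
simulate_flicker_train <- function(spec, frequency, cutoff = 8, depth = 1,
                                   block_duration = 10) {
  stopifnot(inherits(spec, "cell_spec"))
  if (frequency <= 0) stop("flicker frequency must be positive")
  stopifnot(depth >= 0, depth <= 1, cutoff > 0)
  r0 <- spec$profile$baseline_rate
  m <- depth / sqrt(1 + (frequency / cutoff)^2)
  rmax <- r0 * (1 + m)
  blocks <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    blocks[[b]] <- if (rmax <= 0) numeric(0) else {
      old <- .Random.seed_store()
      set.seed(split_seed(spec$seed, 1000 + b))
      n <- stats::rpois(1, rmax * block_duration)
      cand <- sort(stats::runif(n, 0, block_duration))
      rate <- r0 * (1 + m * sin(2 * pi * frequency * cand))
      keep <- stats::runif(n) < rate / rmax
      .Random.seed_restore(old)
      cand[keep]
    }
  }
  out <- spike_train(blocks, block_duration)
  attr(out, "modulation_depth") <- m
  attr(out, "frequency") <- frequency
  out
}
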