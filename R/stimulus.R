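#' Stimulus epoch within a recording block
#'
#' Describes one light stimulus presented inside a repeated recording block.
#' Defaults follow the standard spot-stimulation protocol: 2 s blocks, flash
#' onset 100 ms after block start, 300 ms stimulus duration, 5 repeated
#' blocks, spot diameter 300 um at 6.9 cd*s/m^2.
#'
#' @param onset stimulus onset, seconds from block start
#' @param offset stimulus offset, seconds from block start
#' @param block_duration block length in seconds
#' @param spot_size spot diameter in micrometres
#' @param intensity stimulus intensity, log cd*s/m^2 (6.9 cd*s/m^2 is
#'   approximately 0.84 on that scale; stored as given)
#' @param frequency flicker frequency in Hz, or `NA` for single flashes
#' @param n_blocks number of repeated blocks averaged into one PSTH
#' @return an object of class `stimulus_epoch`
#' @export
stimulus_epoch <- function(onset = 0.1, offset = 0.4, block_duration = 2,
                           spot_size = 300, intensity = 6.9, frequency = NA_real_,
                           n_blocks = 5) {
  if (!is.numeric(onset) || !is.numeric(offset) || offset <= onset)
    stop("stimulus offset must come after onset")
  if (block_duration < offset)
    stop("block_duration must cover the stimulus offset")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  structure(list(onset = onset, offset = offset,
                 block_duration = block_duration,
                 spot_size = spot_size, intensity = intensity,
                 frequency = frequency, n_blocks = n_blocks),
            class = "stimulus_epoch")
}

#' @export
print.stimulus_epoch <- function(x, ...) {
  cat(sprintf("<stimulus_epoch> onset %.3f s, offset %.3f s, block %.1f s, %d block(s)\n",
              x$onset, x$offset, x$block_duration, x$n_blocks))
  invisible(x)
}

#' Stimulus series definition
#'
#' An ordered set of stimulus levels of one kind. Defaults reproduce the
#' standard protocols: spot sizes 75-1700 um at constant intensity,
#' intensities -4.0 to 2.0 log cd*s/m^2 at a constant 300 um spot, and
#' flicker frequencies 1-15 Hz at 300 um and constant intensity.
#'
#' @param kind one of `"spot_size"`, `"intensity"`, `"flicker"`
#' @param levels strictly increasing stimulus values (um, log cd*s/m^2 or Hz);
#'   `NULL` selects the protocol default for `kind`
#' @param fixed_params named list of held-constant stimulus values
#' @return an object of class `stimulus_series`
#' @export
stimulus_series <- function(kind = c("spot_size", "intensity", "flicker"),
                            levels = NULL, fixed_params = list()) {
  kind <- match.arg(kind)
  if (is.null(levels)) {
    levels <- switch(kind,
      spot_size = c(75, 175, 300, 600, 1000, 1700),
      intensity = seq(-4, 2, by = 1),
      flicker   = c(1, 2, 3, 5, 7, 10, 12, 15))
  }
  if (any(diff(levels) <= 0)) stop("series levels must be strictly increasing")
  defaults <- switch(kind,
    spot_size = list(intensity = 6.9),
    intensity = list(spot_size = 300),
    flicker   = list(spot_size = 300, intensity = 6.9))
  fixed_params <- utils::modifyList(defaults, fixed_params)
  structure(list(kind = kind, levels = levels, fixed_params = fixed_params),
            class = "stimulus_series")
}
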