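#' Bias index of a cell's ON/OFF balance
#'
#' `BI = (A1 - A2) / (A1 + A2)`. Negative baseline-corrected amplitudes are
#' clamped to zero first so the index stays in `[-1, 1]`: +1 is a pure ON
#' cell, -1 pure OFF, 0 a balanced ON-OFF cell.
#'
#' @param A1,A2 baseline-corrected ON and OFF peak amplitudes, Hz
#' @return the bias index, or `NA` with a `"non_responsive"` attribute when
#'   both clamped amplitudes are zero
#' @export
bias_index <- function(A1, A2) {
  a1 <- pmax(A1, 0); a2 <- pmax(A2, 0)
  out <- ifelse(a1 + a2 > 0, (a1 - a2) / (a1 + a2), NA_real_)
  if (anyNA(out)) attr(out, "non_responsive") <- which(is.na(out))
  out
}

#' Classify response polarity from the bias index
#'
#' @param BI bias index values
#' @param thresholds `c(lower, upper)`; BI at or above the upper threshold
#'   is ON, at or below the lower is OFF, in between ON-OFF. Default
#'   `c(-1/3, 1/3)` (tertile split of the BI range)
#' @return character vector: `"ON"`, `"OFF"`, `"ON-OFF"` or
#'   `"non-responsive"` for `NA` input
#' @export
classify_polarity <- function(BI, thresholds = c(-1 / 3, 1 / 3)) {
  if (thresholds[1] >= thresholds[2])
    stop("lower threshold must be below upper threshold")
  out <- ifelse(is.na(BI), "non-responsive",
         ifelse(BI >= thresholds[2], "ON",
         ifelse(BI <= thresholds[1], "OFF", "ON-OFF")))
  as.character(out)
}

#' Classify ON-cell kinetics from the response duration
#'
#' ON cells with a response duration below 200 ms are transient, above
#' sustained. The boundary value 200 ms and censored durations (no
#' amplitude/e crossing observed) are classified sustained.
#'
#' @param A1tau2 response duration, ms (`NA` = censored)
#' @param boundary_ms default 200
#' @return `"transient"` or `"sustained"`
#' @export
classify_kinetics <- function(A1tau2, boundary_ms = 200) {
  ifelse(!is.na(A1tau2) & A1tau2 < boundary_ms, "transient", "sustained")
}

#' Classify a set of cells from their response metrics
#'
#' @param metrics data frame with columns `A1`, `A2`, `A1tau2` (and
#'   optionally `cell`)
#' @param thresholds polarity thresholds, see [classify_polarity()]
#' @param boundary_ms kinetics boundary, see [classify_kinetics()]
#' @return data frame with `cell`, `BI`, `polarity`, `kinetics` (only ON
#'   cells get a kinetics label; others are `"n/a"`)
#' @export
classify_cells <- function(metrics, thresholds = c(-1 / 3, 1 / 3),
                           boundary_ms = 200) {
  stopifnot(all(c("A1", "A2", "A1tau2") %in% names(metrics)))
  BI <- as.numeric(bias_index(metrics$A1, metrics$A2))
  polarity <- classify_polarity(BI, thresholds)
  kinetics <- ifelse(polarity == "ON",
                     classify_kinetics(metrics$A1tau2, boundary_ms), "n/a")
  data.frame(cell = if (!is.null(metrics$cell)) metrics$cell
             else seq_len(nrow(metrics)),
             BI = BI, polarity = polarity, kinetics = kinetics,
             stringsAsFactors = FALSE)
}
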