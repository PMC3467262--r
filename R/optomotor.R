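#' Michelson contrast of a grating
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)`, dimensionless in `[0, 1]`, invariant to
#' a common luminance scale factor.
#'
#' @param lum_max,lum_min screen luminances in cd/m^2,
#'   `lum_max >= lum_min >= 0`, not both zero
#' @return contrast
#' @export
michelson_contrast <- function(lum_max, lum_min) {
  if (any(lum_min < 0) || any(lum_max < lum_min))
    stop("require lum_max >= lum_min >= 0")
  if (any(lum_max + lum_min == 0))
    stop("contrast undefined for zero total luminance")
  (lum_max - lum_min) / (lum_max + lum_min)
}

#' Contrast sensitivity from a threshold contrast
#'
#' The reciprocal of the threshold Michelson contrast.
#'
#' @param threshold_contrast in `(0, 1]`
#' @return sensitivity (>= 1)
#' @export
contrast_sensitivity <- function(threshold_contrast) {
  if (any(threshold_contrast <= 0))
    stop("threshold contrast must be positive (sensitivity would be infinite)")
  if (any(threshold_contrast > 1))
    stop("threshold contrast cannot exceed 1")
  1 / threshold_contrast
}

#' Threshold contrast as a percentage
#'
#' Converts a contrast sensitivity to the corresponding percent Michelson
#' contrast (`100 / sensitivity`), the conventional reporting style.
#'
#' @param sensitivity contrast sensitivity
#' @param digits decimals to round the percentage to (default 1)
#' @return percent contrast
#' @export
contrast_percent <- function(sensitivity, digits = 1) {
  round(100 / sensitivity, digits)
}

#' Summarize a contrast-sensitivity function
#'
#' Per-frequency sensitivity (group mean +/- SEM when replicates are given),
#' the peak spatial frequency, and an optional two-group comparison per
#' frequency by t-test.
#'
#' @param data data frame with columns `spatial_frequency`,
#'   `threshold_contrast`, and optionally `group` and `animal`
#' @param var_equal use the pooled-variance t-test instead of Welch
#'   (default `FALSE`)
#' @return list: `table` (frequency, per-group mean sensitivity, SEM, n,
#'   and `p` when two groups are present), `peak_frequency` (`NA` if fewer
#'   than two frequencies)
#' @export
summarize_csf <- function(data, var_equal = FALSE) {
  stopifnot(all(c("spatial_frequency", "threshold_contrast") %in% names(data)))
  data$sensitivity <- contrast_sensitivity(data$threshold_contrast)
  if (is.null(data$group)) data$group <- "all"
  groups <- unique(data$group)
  freqs <- sort(unique(data$spatial_frequency))
  rows <- lapply(freqs, function(f) {
    d <- data[data$spatial_frequency == f, ]
    out <- data.frame(spatial_frequency = f)
    for (g in groups) {
      s <- d$sensitivity[d$group == g]
      out[[paste0("mean_", g)]] <- mean(s)
      out[[paste0("sem_", g)]] <- if (length(s) > 1)
        stats::sd(s) / sqrt(length(s)) else NA_real_
      out[[paste0("n_", g)]] <- length(s)
    }
    if (length(groups) == 2) {
      s1 <- d$sensitivity[d$group == groups[1]]
      s2 <- d$sensitivity[d$group == groups[2]]
      out$p <- if (length(s1) > 1 && length(s2) > 1)
        stats::t.test(s1, s2, var.equal = var_equal)$p.value else NA_real_
    }
    out
  })
  tab <- do.call(rbind, rows)
  peak <- if (length(freqs) < 2) NA_real_ else {
    overall <- vapply(freqs, function(f)
      mean(data$sensitivity[data$spatial_frequency == f]), numeric(1))
    freqs[which.max(overall)]
  }
  list(table = tab, peak_frequency = peak)
}
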