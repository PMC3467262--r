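#' Read a spike timestamp table
#'
#' Expects delimited text with header columns `unit_id`, `block`,
#' `timestamp_s`. Malformed rows are rejected with their line numbers.
#'
#' @param path file path
#' @param sep field separator (default tab)
#' @param block_duration block length in seconds; default is inferred as
#'   the ceiling of the largest timestamp
#' @return named list of [spike_train()]s, one per unit
#' @export
read_spike_table <- function(path, sep = "\t", block_duration = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  need <- c("unit_id", "block", "timestamp_s")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  ts <- suppressWarnings(as.numeric(df$timestamp_s))
  blk <- suppressWarnings(as.integer(df$block))
  bad <- which(is.na(ts) | is.na(blk))
  if (length(bad))
    stop("malformed row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  if (is.null(block_duration)) block_duration <- ceiling(max(ts, 0))
  out <- lapply(split(seq_len(nrow(df)), df$unit_id), function(idx) {
    blocks <- split(ts[idx], blk[idx])
    nb <- max(blk[idx])
    full <- lapply(seq_len(nb), function(b)
      sort(blocks[[as.character(b)]] %||% numeric(0)))
    spike_train(full, block_duration)
  })
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spike train collection to a delimited table
#'
#' @param trains named list of [spike_train()]s
#' @param path output path
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_spike_table <- function(trains, path, sep = "\t") {
  rows <- lapply(names(trains), function(u) {
    tr <- trains[[u]]
    do.call(rbind, lapply(seq_len(tr$n_blocks), function(b) {
      if (!length(tr$blocks[[b]])) return(NULL)
      data.frame(unit_id = u, block = b,
                 timestamp_s = tr$blocks[[b]])
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(unit_id = character(), block = integer(),
                     timestamp_s = numeric())
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a two-column (time, value) trace file
#'
#' @param path file path
#' @param sep separator
#' @return data frame with `time`, `value`
#' @export
read_trace_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time", "value") %in% names(df)))
    stop("trace file needs columns 'time' and 'value'")
  df
}

#' @rdname read_trace_table
#' @param time,value numeric vectors
#' @export
write_trace_table <- function(time, value, path, sep = "\t") {
  utils::write.table(data.frame(time = time, value = value), path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' All tunable constants of the pipeline with the protocol defaults.
#' Configurations round-trip losslessly through JSON.
#'
#' @param ... overrides of the default fields
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "retinaresp-out",
    stimulus = list(onset = 0.1, offset = 0.4, block_duration = 2,
                    n_blocks = 5, spot_size = 300, intensity = 6.9),
    psth = list(bin_width_ms = 1, smoothing_sigma_ms = 25,
                baseline_window_ms = 100),
    detection = list(low_cut = 300, high_cut = 5000, order = 2,
                     k_sigma = 2.8, refractory_ms = 1,
                     sampling_rate = 20000),
    classification = list(bi_lower = -1 / 3, bi_upper = 1 / 3,
                          kinetics_boundary_ms = 200),
    erg = list(a_window = c(5, 50), b_window_end = 150, smooth_ms = 1.5,
               fusion_criterion_k = 3,
               flicker_frequencies = c(0.5, 1, 2, 3, 5, 7, 10, 12, 15,
                                       18, 20, 30)),
    optomotor = list(spatial_frequencies = c(0.031, 0.064, 0.092, 0.103,
                                             0.192, 0.272),
                     lum_max = 152.13, lum_min = 0.22))
  cfg <- utils::modifyList(defaults, list(...))
  structure(cfg, class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`
#' @param path JSON file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}
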