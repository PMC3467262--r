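#' Run the analysis pipeline
#'
#' File-based pipeline driving all stages on the default synthetic fixture
#' (or on files previously produced): `simulate` writes the 60-cell spike
#' tables and ERG traces; `detect` simulates a raw trace and runs band-pass
#' plus threshold detection; `psth` and `classify` parameterize and label
#' the cells; `series` runs a spot-size series with normalization; `erg`
#' extracts single-flash and flicker metrics; `optomotor` summarizes a
#' contrast-sensitivity table if present. Outputs are UTF-8 delimited text
#' and JSON; identical config + seed gives byte-identical tables.
#'
#' @param config an [analysis_config()]
#' @param stage one of `"simulate"`, `"detect"`, `"psth"`, `"classify"`,
#'   `"series"`, `"erg"`, `"optomotor"`, `"all"`
#' @return named list of result-file paths, plus the JSON report path
#' @export
run_pipeline <- function(config = analysis_config(), stage = "all") {
  stages <- c("simulate", "detect", "psth", "classify", "series", "erg",
              "optomotor", "all")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(stages, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- if (stage == "all")
    c("simulate", "detect", "psth", "classify", "series", "erg")
  else stage
  epoch <- do.call(stimulus_epoch, config$stimulus[
    c("onset", "offset", "block_duration", "spot_size", "intensity",
      "n_blocks")])
  out <- list()
  report <- list(package_version = as.character(utils::packageVersion("retinaresp")),
                 seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    info <- list(...)
    report$stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(info), sep = "=", collapse = " ")))
  }

  path <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% run) {
    specs <- default_population(config$seed,
                                n_blocks = config$stimulus$n_blocks)
    trains <- lapply(specs, simulate_spike_train, epoch = epoch)
    out$spikes <- write_spike_table(trains, path("spike_trains.tsv"))
    truth <- data.frame(cell = names(specs),
                        true_class = vapply(specs, `[[`, "", "true_class"))
    utils::write.table(truth, path("ground_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$truth <- path("ground_truth.tsv")
    log_stage("simulate", n_cells = length(specs),
              n_spikes = sum(vapply(trains, function(t)
                sum(lengths(t$blocks)), numeric(1))))
  }

  if ("detect" %in% run) {
    det <- config$detection
    sp <- cell_spec("ON-transient",
                    rate_profile(15, on_amp = 60), n_blocks = 1,
                    seed = split_seed(config$seed, 5))
    train <- simulate_spike_train(sp, epoch)
    trace <- simulate_raw_trace(train, waveform_amp = 50, noise_sd = 10,
                                sampling_rate = det$sampling_rate,
                                seed = config$seed)
    fsp <- filter_spec(det$low_cut, det$high_cut, det$order)
    filt <- bandpass_filter(trace, fsp)
    detected <- filter_and_detect(trace, fsp, k_sigma = det$k_sigma,
                                  refractory_ms = det$refractory_ms)
    sc <- score_detection(detected$blocks[[1]], attr(trace, "true_times"))
    write_trace_table(seq_along(filt$samples) / filt$sampling_rate,
                      filt$samples, path("filtered_trace.tsv"))
    out$detection <- path("detected_spikes.tsv")
    write_spike_table(list(unit1 = detected), out$detection)
    log_stage("detect", n_true = length(attr(trace, "true_times")),
              n_detected = length(detected$blocks[[1]]),
              recall = round(sc$recall, 3), precision = round(sc$precision, 3))
  }

  if (any(c("psth", "classify") %in% run)) {
    spike_file <- path("spike_trains.tsv")
    if (!file.exists(spike_file))
      stop("stage needs ", spike_file, "; run the 'simulate' stage first")
    trains <- read_spike_table(spike_file,
                               block_duration = epoch$block_duration)
    metrics <- do.call(rbind, lapply(names(trains), function(id) {
      m <- response_metrics(trains[[id]], epoch,
                            bin_width_ms = config$psth$bin_width_ms,
                            sigma_ms = config$psth$smoothing_sigma_ms)
      data.frame(cell = id, baseline = m$baseline, A1 = m$A1, L1 = m$L1,
                 A1tau2 = ifelse(is.na(m$A1tau2), NA_real_, m$A1tau2),
                 A2 = m$A2, L2 = m$L2,
                 A2tau2 = ifelse(is.na(m$A2tau2), NA_real_, m$A2tau2))
    }))
    utils::write.table(metrics, path("psth_metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$metrics <- path("psth_metrics.tsv")
    log_stage("psth", n_cells = nrow(metrics))
    if ("classify" %in% run || stage == "all") {
      cls <- classify_cells(metrics,
                            thresholds = c(config$classification$bi_lower,
                                           config$classification$bi_upper),
                            boundary_ms = config$classification$kinetics_boundary_ms)
      utils::write.table(cls, path("classification.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      out$classification <- path("classification.tsv")
      log_stage("classify", n_cells = nrow(cls),
                n_on = sum(cls$polarity == "ON"),
                n_off = sum(cls$polarity == "OFF"),
                n_onoff = sum(cls$polarity == "ON-OFF"))
    }
  }

  if ("series" %in% run) {
    series <- stimulus_series("spot_size")
    # size tuning emulated as a Gaussian in log-size around the preferred size
    sp_seed <- split_seed(config$seed, 11)
    tuning <- function(sz) exp(-((log(sz) - log(300)) / 0.9)^2 / 2)
    trains <- lapply(stats::setNames(series$levels, series$levels), function(sz) {
      prof <- rate_profile(10, on_amp = 70 * tuning(sz))
      simulate_spike_train(cell_spec("ON-transient", prof,
                                     n_blocks = config$stimulus$n_blocks,
                                     seed = split_seed(sp_seed, round(sz))),
                           epoch)
    })
    res <- analyze_series(trains, series, epoch)
    tab <- cbind(res$metrics, normalized_A = res$normalized_A)
    utils::write.table(tab, path("series_spot_size.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$series <- path("series_spot_size.tsv")
    log_stage("series", n_levels = length(series$levels),
              preferred_level = res$preferred_level)
  }

  if ("erg" %in% run) {
    tr <- simulate_erg(erg_spec(noise_sd = 5), seed = config$seed)
    m <- measure_single_flash(tr, config$erg$a_window,
                              config$erg$b_window_end, config$erg$smooth_ms)
    flick <- simulate_erg_flicker(config$erg$flicker_frequencies,
                                  seed = config$seed)
    fa <- analyze_flicker(flick$traces, flick$frequencies,
                          criterion_k = config$erg$fusion_criterion_k)
    erg_out <- list(single_flash = m,
                    fusion_frequency = fa$fusion_frequency,
                    flicker = fa$table)
    jsonlite::write_json(erg_out, path("erg_metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$erg <- path("erg_metrics.json")
    log_stage("erg", b_amplitude = round(m$b_amplitude, 1),
              b_latency = m$b_latency,
              fusion = fa$fusion_frequency)
  }

  if ("optomotor" %in% run) {
    thr_file <- path("contrast_thresholds.tsv")
    if (!file.exists(thr_file))
      stop("optomotor stage needs a threshold table at ", thr_file,
           " (columns animal, group, spatial_frequency, threshold_contrast)")
    thr <- utils::read.table(thr_file, header = TRUE, sep = "\t")
    csf <- summarize_csf(thr)
    utils::write.table(csf$table, path("csf_summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$optomotor <- path("csf_summary.tsv")
    log_stage("optomotor", peak_frequency = csf$peak_frequency)
  }

  report_path <- path("report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  out$report <- report_path
  invisible(out)
}
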