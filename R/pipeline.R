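#' Analysis configuration
#'
#' Collects every parameter of the full analysis. `recording` may be an
#' [mea_recording()] object or the path to a multi-column signal CSV (in
#' which case `layout` must be a layout data frame or CSV path); file
#' existence is checked here, before any signal is touched.
#'
#' @param recording an [mea_recording()] or signal CSV path.
#' @param layout layout data frame or CSV path (ignored when `recording`
#'   is already an object).
#' @param filter a [filter_config()].
#' @param cluster_gap beat cluster gap in s (default 0.05).
#' @param min_electrodes spatial eligibility threshold (default 4).
#' @param ibr_dt IBR bin width in s (default 0.5).
#' @param entropy_bin slowness histogram bin size in s/cm (default 0.005).
#' @param dfa_n_grid DFA segment lengths (default `dfa_grid()`).
#' @param epoch_pre,epoch_post epoch window in s (defaults 10, 30).
#' @param out_dir optional output directory for the JSON report.
#' @param seed optional seed recorded in the report (the analysis itself is
#'   deterministic).
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(recording, layout = NULL,
                            filter = filter_config(), cluster_gap = 0.05,
                            min_electrodes = 4, ibr_dt = 0.5,
                            entropy_bin = 0.005, dfa_n_grid = dfa_grid(),
                            epoch_pre = 10, epoch_post = 30,
                            out_dir = NULL, seed = NULL) {
  if (is.character(recording)) {
    if (!file.exists(recording))
      stop("recording file not found: ", recording)
    if (is.character(layout) && !file.exists(layout))
      stop("layout file not found: ", layout)
    if (is.null(layout)) stop("'layout' is required with a recording path")
  } else if (!inherits(recording, "mea_recording")) {
    stop("'recording' must be an mea_recording or a file path")
  }
  structure(list(recording = recording, layout = layout, filter = filter,
                 cluster_gap = cluster_gap, min_electrodes = min_electrodes,
                 ibr_dt = ibr_dt, entropy_bin = entropy_bin,
                 dfa_n_grid = dfa_n_grid, epoch_pre = epoch_pre,
                 epoch_post = epoch_post, out_dir = out_dir, seed = seed),
            class = "analysis_config")
}

#' Run the full analysis pipeline on one recording
#'
#' detect -> beats -> spatial -> temporal -> stretch: conditions and
#' detects every channel, clusters activations into beats, fits per-beat
#' slowness vectors, computes the slowness-distribution entropy, activation
#' PCA, the IBI/interbeat-slowness-difference Spearman correlation, the DFA
#' exponent of the IBI series and, when the recording carries motor pulses,
#' the stretch/release epoch averages of the instantaneous beat rate.
#'
#' @param config an [analysis_config()].
#' @return object of class `"recording_report"`; also written as
#'   `report.json` under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  rec <- config$recording
  if (is.character(rec))
    rec <- read_recording_csv(rec, config$layout)
  if (!is.null(config$seed)) set.seed(config$seed)

  events <- detect_recording(rec, config$filter)
  bs <- cluster_beats(events, gap = config$cluster_gap,
                      min_electrodes = config$min_electrodes,
                      electrodes = as.character(rec$layout$electrode))
  stab <- slowness_table(bs, rec$layout)
  ent <- slowness_entropy(stab, bin_size = config$entropy_bin)
  pca <- tryCatch(pca_activation(bs), error = function(e) NULL)
  dres <- tryCatch(dfa(bs$ibi, config$dfa_n_grid), error = function(e) NULL)
  sdiff <- interbeat_slowness_diff(stab)
  corr <- tryCatch(spearman_quantile_correlation(bs$ibi, sdiff),
                   error = function(e) NULL)
  ibr <- resample_ibr(bs, dt = config$ibr_dt)

  motor <- parse_motor_events(rec$event_channel, rec$sampling_rate)
  epochs <- list()
  for (kind in intersect(c("stretch", "release"), motor$kind))
    epochs[[kind]] <- epoch_average(ibr, motor, kind,
                                    pre_s = config$epoch_pre,
                                    post_s = config$epoch_post)

  report <- structure(list(
    n_beats = nrow(bs$beats),
    mean_ibi = mean(bs$ibi),
    ibi = bs$ibi,
    beats = bs,
    slowness = stab,
    entropy = ent,
    pca = pca,
    dfa = dres,
    spearman = corr,
    ibr = ibr,
    motor_events = motor,
    epochs = epochs,
    parameters = config[setdiff(names(config), "recording")]),
    class = "recording_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.recording_report <- function(x, ...) {
  cat("<recording_report>\n")
  cat(sprintf("  beats: %d, mean IBI %.3f s (rate %.2f Hz)\n",
              x$n_beats, x$mean_ibi, 1 / x$mean_ibi))
  cat(sprintf("  slowness entropy E = %.3f nats (%d bins)\n",
              x$entropy$E, x$entropy$occupied_bins))
  if (!is.null(x$dfa))
    cat(sprintf("  DFA alpha = %.3f\n", x$dfa$alpha))
  if (!is.null(x$pca))
    cat(sprintf("  PCA: first two components %.1f%% of variance\n",
                100 * x$pca$cumulative_two))
  if (!is.null(x$spearman))
    cat(sprintf("  Spearman rho(IBI, slowness diff) = %.3f\n",
                x$spearman$rho))
  for (k in names(x$epochs))
    cat(sprintf("  %s: mean peak fold-change %.2f over %d repeats\n",
                k, x$epochs[[k]]$mean_peak, x$epochs[[k]]$n_repeats))
  invisible(x)
}

#' Write a recording report as JSON
#'
#' Serializes the numeric summary of a [run_pipeline()] report (scalar
#' markers, IBI series, slowness table, epoch summaries, parameters) with
#' full precision, so reruns with identical inputs produce byte-identical
#' files.
#'
#' @param report a `"recording_report"`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "recording_report"))
  ep <- lapply(report$epochs, function(e)
    list(kind = e$kind, n_repeats = e$n_repeats, mean_peak = e$mean_peak,
         peak_time = e$peak_time, peaks = e$peaks,
         time_axis = e$time_axis, mean_trace = e$mean_trace))
  out <- list(
    n_beats = report$n_beats,
    mean_ibi = report$mean_ibi,
    ibi = report$ibi,
    slowness = report$slowness,
    entropy = list(E = report$entropy$E,
                   occupied_bins = report$entropy$occupied_bins,
                   bin_size = report$entropy$bin_size),
    dfa = if (!is.null(report$dfa))
      list(n = report$dfa$n, df = report$dfa$df, alpha = report$dfa$alpha,
           r_squared = report$dfa$r_squared),
    pca = if (!is.null(report$pca))
      list(variance_fractions = report$pca$variance_fractions,
           cumulative_two = report$pca$cumulative_two),
    spearman = if (!is.null(report$spearman))
      list(rho = report$spearman$rho, n = report$spearman$n),
    motor_events = report$motor_events,
    epochs = ep,
    parameters = list(
      cluster_gap = report$parameters$cluster_gap,
      min_electrodes = report$parameters$min_electrodes,
      ibr_dt = report$parameters$ibr_dt,
      entropy_bin = report$parameters$entropy_bin,
      dfa_n_grid = report$parameters$dfa_n_grid,
      epoch_pre = report$parameters$epoch_pre,
      epoch_post = report$parameters$epoch_post,
      seed = report$parameters$seed))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
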