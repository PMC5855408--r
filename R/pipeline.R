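# session cache for the built-in template (integration is deterministic,
# so caching only saves time)
.template_cache <- new.env(parent = emptyenv())

#' The built-in reaction-diffusion PPG template
#'
#' Integrates the oscillator at the published parameters and extracts the
#' normalised one-period template (cached per session; the computation is
#' deterministic).
#'
#' @param n_samples Template length Ns.
#' @param params An [rd_params()].
#' @param t_end,dt,transient Integration settings, see [integrate_rd()]
#'   and [extract_template()].
#' @return A `ppg_template`.
#' @export
default_template <- function(n_samples = 512, params = rd_params(),
                             t_end = 100, dt = 1e-3, transient = 30) {
  key <- paste(c(unlist(params), n_samples, t_end, dt, transient), collapse = "|")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  traj <- integrate_rd(params, t_end = t_end, dt = dt)
  tem <- extract_template(traj, n_samples = n_samples, transient = transient)
  .template_cache[[key]] <- tem
  tem
}

#' Pipeline configuration
#'
#' Gathers every tunable of the screening pipeline with the published
#' defaults where the source prints them: PPG compliance threshold 0.90,
#' ECG AND-gate threshold 0.80, the Table-1 FIR specifications, and the
#' oscillator parameter set of [rd_params()].
#'
#' @param fs Sampling rate in Hz.
#' @param ppg_threshold PPG compliance threshold.
#' @param ecg_threshold ECG AND-gate threshold.
#' @param n_samples Template/rescale length Ns.
#' @param correlation_mode `"pearson"` or `"as_printed"`.
#' @param strict_all_lags Require every lag (not the mean) to pass.
#' @param refractory,prominence_frac Segmentation guards, see
#'   [detect_onsets()].
#' @param min_beat_duration Minimum beat length in seconds.
#' @param rd Oscillator parameters ([rd_params()]).
#' @param ppg_filter,ecg_filter Filter spec pairs
#'   ([default_filter_specs()]).
#' @param distance Probe separation in metres (PWV).
#' @param seed Integer seed recorded in reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 1000, ppg_threshold = 0.90,
                            ecg_threshold = 0.80, n_samples = 512,
                            correlation_mode = c("pearson", "as_printed"),
                            strict_all_lags = FALSE,
                            refractory = 0.3, prominence_frac = 0.1,
                            min_beat_duration = 0.25,
                            rd = rd_params(),
                            ppg_filter = default_filter_specs("ppg", fs),
                            ecg_filter = default_filter_specs("ecg", fs),
                            distance = 0.5, seed = 1) {
  correlation_mode <- match.arg(correlation_mode)
  stopifnot(ppg_threshold >= -1, ppg_threshold <= 1,
            ecg_threshold >= -1, ecg_threshold <= 1, fs > 0)
  structure(list(fs = fs, ppg_threshold = ppg_threshold,
                 ecg_threshold = ecg_threshold, n_samples = n_samples,
                 correlation_mode = correlation_mode,
                 strict_all_lags = strict_all_lags,
                 refractory = refractory, prominence_frac = prominence_frac,
                 min_beat_duration = min_beat_duration, rd = rd,
                 ppg_filter = ppg_filter, ecg_filter = ecg_filter,
                 distance = distance, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the complete screening pipeline on a record
#'
#' Pre-filtering, first-derivative segmentation, template scoring of every
#' PPG beat, ECG AND-gate validation of the compliant beats (when an ECG
#' channel is present), and medical indicators over the accepted beats.
#' A second-site PPG channel, when present, is segmented the same way to
#' obtain pulse transit time and pulse wave velocity.
#'
#' @param record A `labeled_record`, or any list with elements `ppg`
#'   (required), `ecg` and `site2_ppg` (optional), each a
#'   [sampled_signal()].
#' @param config A [pipeline_config()].
#' @param template A `ppg_template`; default built from `config$rd`.
#' @param ecg_ref An [ecg_reference()].
#' @return An object of class `run_report`: list with `counts`, `onsets`,
#'   `scored`, `validation`, `indicators`, `accepted_starts` and `config`
#'   scalars.
#' @export
run_pipeline <- function(record, config = pipeline_config(fs = record$ppg$fs),
                         template = NULL, ecg_ref = ecg_reference()) {
  stopifnot(inherits(record$ppg, "sampled_signal"))
  if (is.null(template))
    template <- default_template(config$n_samples, config$rd)

  res <- validate_record(record$ppg, record$ecg, template, ecg_ref, config)

  # final acceptance: PPG compliance, refined by the ECG gate when present
  accepted <- res$scored$start[res$scored$compliant]
  if (!is.null(record$ecg) && nrow(res$validation) > 0)
    accepted <- intersect(accepted, res$validation$start[res$validation$valid])
  acc_idx <- which(res$scored$start %in% accepted)
  acc_beats <- res$beats[acc_idx]

  onsets_site2 <- NULL
  if (!is.null(record$site2_ppg)) {
    s2f <- ppg_bandpass(record$site2_ppg, config$ppg_filter)
    onsets_site2 <- detect_onsets(s2f, config$refractory,
                                  config$prominence_frac) / config$fs
  }
  indicators <- compute_indicators(acc_beats, config$fs, onsets_site2,
                                   config$distance)

  structure(list(
    counts = list(n_onsets = length(res$onsets),
                  n_beats = nrow(res$scored),
                  n_compliant = sum(res$scored$compliant),
                  n_valid = if (nrow(res$validation)) sum(res$validation$valid) else NA_integer_,
                  n_accepted = length(acc_idx)),
    onsets = res$onsets,
    beats = res$beats,
    scored = res$scored,
    validation = res$validation,
    accepted_starts = accepted,
    indicators = indicators,
    config = list(fs = config$fs, ppg_threshold = config$ppg_threshold,
                  ecg_threshold = config$ecg_threshold,
                  n_samples = config$n_samples,
                  correlation_mode = config$correlation_mode,
                  seed = config$seed)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  onsets: %d | beats: %d | compliant: %d | ECG-valid: %s | accepted: %d\n",
              x$counts$n_onsets, x$counts$n_beats, x$counts$n_compliant,
              if (is.na(x$counts$n_valid)) "(no ECG)" else x$counts$n_valid,
              x$counts$n_accepted))
  print(x$indicators)
  invisible(x)
}

#' Read a multichannel record from CSV
#'
#' Expects a header row; an optional `time_s` column carries sample times
#' (the rate is inferred from its median increment), otherwise `fs` must
#' be given. Every remaining column becomes one channel.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz, required when there is no `time_s`
#'   column.
#' @return Named list of [sampled_signal()]s.
#' @export
read_record <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (!ncol(df)) stop("empty record file: ", path)
  t0 <- 0
  if ("time_s" %in% names(df)) {
    tv <- df$time_s
    if (length(tv) < 2) stop("time column too short to infer a rate in ", path)
    fs <- 1 / stats::median(diff(tv))
    t0 <- tv[1]
    df$time_s <- NULL
  }
  if (is.null(fs)) stop("no 'time_s' column in ", path, "; supply 'fs'")
  if (!ncol(df)) stop("no channel columns in ", path)
  out <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (!is.numeric(v)) stop("non-numeric channel '", nm, "' in ", path)
    if (anyNA(v) || any(!is.finite(v)))
      stop("channel '", nm, "' contains NA/Inf in ", path)
    sampled_signal(v, fs, t0 = t0, label = nm)
  })
  names(out) <- names(df)
  out
}

#' Write a record to CSV
#'
#' @param channels Named list of [sampled_signal()]s sharing one rate.
#' @param path Output path.
#' @param time_column Include a `time_s` column.
#' @export
write_record <- function(channels, path, time_column = TRUE) {
  stopifnot(length(channels) >= 1)
  fs <- channels[[1]]$fs
  df <- as.data.frame(lapply(channels, function(s) s$samples))
  if (time_column)
    df <- cbind(time_s = signal_times(channels[[1]]), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a run report
#'
#' JSON round-trips the full report (without the raw beat waveforms); CSV
#' writes the per-beat scored table.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "run_report"))
  if (format == "json") {
    out <- list(counts = report$counts,
                onsets = report$onsets,
                scored = report$scored,
                validation = report$validation,
                accepted_starts = report$accepted_starts,
                indicators = unclass(report$indicators),
                config = report$config)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.csv(report$scored, path, row.names = FALSE)
  }
  invisible(path)
}
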