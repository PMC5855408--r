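#' Mean heart rate from beat onsets
#'
#' @param onset_times Onset times in seconds (>= 2).
#' @return Beats per minute: `60 / mean(inter-beat intervals)`.
#' @export
compute_bpm <- function(onset_times) {
  onset_times <- as.numeric(onset_times)
  if (length(onset_times) < 2) stop("need at least 2 onsets for a heart rate")
  60 / mean(diff(onset_times))
}

#' Time-domain heart-rate variability
#'
#' SDNN (population standard deviation of inter-beat intervals) and RMSSD
#' (root mean square of successive interval differences), both in
#' milliseconds - the standard short-term time-domain HRV summaries.
#'
#' @param onset_times Onset times in seconds (>= 3).
#' @return List with `sdnn_ms` and `rmssd_ms`.
#' @export
compute_hrv <- function(onset_times) {
  onset_times <- as.numeric(onset_times)
  if (length(onset_times) < 3) stop("need at least 3 onsets for HRV")
  ibi <- diff(onset_times) * 1000
  n <- length(ibi)
  sdnn <- sqrt(sum((ibi - mean(ibi))^2) / n)
  rmssd <- sqrt(mean(diff(ibi)^2))
  list(sdnn_ms = sdnn, rmssd_ms = rmssd)
}

#' Augmentation index of one beat
#'
#' Reflection ratio `(diastolic peak amplitude - onset amplitude) /
#' (systolic peak amplitude - onset amplitude)`; lies in \[0, 1\] for
#' normal pulse morphology.
#'
#' @param beat A `segmented_beat` with located fiducials.
#' @return The ratio, or `NA` when the diastolic peak is absent.
#' @export
compute_ai <- function(beat) {
  stopifnot(inherits(beat, "segmented_beat"))
  f <- if (is.null(beat$fiducials)) locate_fiducials(beat) else beat$fiducials
  if (is.na(f$diastolic_peak)) return(NA_real_)
  s <- beat$samples
  (s[f$diastolic_peak] - s[f$onset]) / (s[f$systolic_peak] - s[f$onset])
}

#' Pulse transit time and pulse wave velocity from two sites
#'
#' Onsets from the two probes are paired by nearest match within half the
#' site-1 median inter-beat interval (foot-to-foot timing); PTT is the
#' mean paired delay and PWV the probe separation divided by it.
#'
#' @param onsets_site1,onsets_site2 Onset times in seconds at the two
#'   body sites.
#' @param distance Probe separation in metres.
#' @return List with `ptt_ms`, `pwv_m_s`, `n_pairs` and a
#'   `nonpositive_delay` flag (PWV is `NA` when the mean delay is not
#'   positive).
#' @export
compute_ptt_pwv <- function(onsets_site1, onsets_site2, distance) {
  o1 <- as.numeric(onsets_site1); o2 <- as.numeric(onsets_site2)
  if (length(o1) < 2 || length(o2) < 1) stop("too few onsets to pair")
  half_ibi <- stats::median(diff(o1)) / 2
  delays <- c()
  for (t1 in o1) {
    j <- which.min(abs(o2 - t1))
    if (abs(o2[j] - t1) <= half_ibi) delays <- c(delays, o2[j] - t1)
  }
  if (!length(delays)) stop("no pairable beats between the two sites")
  ptt_s <- mean(delays)
  nonpos <- ptt_s <= 0
  list(ptt_ms = ptt_s * 1000,
       pwv_m_s = if (nonpos) NA_real_ else distance / ptt_s,
       n_pairs = length(delays),
       nonpositive_delay = nonpos)
}

#' Indicator report over the accepted beats
#'
#' Computes BPM, HRV and the mean augmentation index over the beats that
#' survived screening (clean-signal requirement for medical indicators);
#' adds PTT/PWV when a second-site onset train is given. Rejected beats
#' leave gaps in the accepted sequence, so rate and variability use only
#' inter-beat intervals between beats that are *adjacent in the record*
#' -- an interval spanning a rejected beat is not a cardiac interval.
#'
#' @param beats List of accepted `segmented_beat`s.
#' @param fs Sampling rate in Hz.
#' @param onsets_site2 Optional second-site onset times in seconds.
#' @param distance Probe separation in metres (for PWV).
#' @return List of class `indicator_report`.
#' @export
compute_indicators <- function(beats, fs, onsets_site2 = NULL, distance = 0.5) {
  n <- length(beats)
  rep <- list(n_beats_used = n, bpm = NA_real_, sdnn_ms = NA_real_,
              rmssd_ms = NA_real_, ai = NA_real_, ptt_ms = NA_real_,
              pwv_m_s = NA_real_)
  if (n >= 2) {
    onsets <- vapply(beats, function(b) b$start_index, 0L) / fs
    ends <- vapply(beats, function(b) b$start_index + length(b$samples), 0L) / fs
    adjacent <- abs(onsets[-1] - ends[-n]) < 1e-9
    ibi <- diff(onsets)[adjacent]
    if (length(ibi) >= 1) rep$bpm <- 60 / mean(ibi)
    if (length(ibi) >= 2) {
      ms <- ibi * 1000
      rep$sdnn_ms <- sqrt(sum((ms - mean(ms))^2) / length(ms))
      # successive differences only within runs of adjacent beats
      run <- cumsum(c(TRUE, !adjacent))[-n][adjacent]
      dd <- diff(ms)[diff(run) == 0]
      if (length(dd)) rep$rmssd_ms <- sqrt(mean(dd^2))
    }
    ai <- vapply(beats, compute_ai, 0)
    rep$ai <- if (all(is.na(ai))) NA_real_ else mean(ai, na.rm = TRUE)
    if (!is.null(onsets_site2) && length(onsets_site2) >= 1) {
      pp <- tryCatch(compute_ptt_pwv(onsets, onsets_site2, distance),
                     error = function(e) NULL)
      if (!is.null(pp)) {
        rep$ptt_ms <- pp$ptt_ms
        rep$pwv_m_s <- pp$pwv_m_s
      }
    }
  }
  structure(rep, class = "indicator_report")
}

#' @export
print.indicator_report <- function(x, ...) {
  cat("<indicator_report>\n")
  cat(sprintf("  beats used : %d\n", x$n_beats_used))
  cat(sprintf("  BPM        : %s\n", fmt_na(x$bpm)))
  cat(sprintf("  SDNN       : %s ms\n", fmt_na(x$sdnn_ms)))
  cat(sprintf("  RMSSD      : %s ms\n", fmt_na(x$rmssd_ms)))
  cat(sprintf("  AI         : %s\n", fmt_na(x$ai)))
  if (!is.na(x$ptt_ms)) {
    cat(sprintf("  PTT        : %.1f ms\n", x$ptt_ms))
    cat(sprintf("  PWV        : %s m/s\n", fmt_na(x$pwv_m_s)))
  }
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
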