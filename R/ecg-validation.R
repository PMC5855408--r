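#' Synthetic ECG reference pattern
#'
#' One PQRST pulse built as a sum of five Gaussians (P, Q, R, S, T), a
#' standard synthetic-ECG parameterisation, evaluated over a one-beat
#' window and min-max normalised to \[0, 1\]. Serves as the "conventional
#' ECG standard pattern" of the validation stage; user-supplied references
#' can be loaded with [read_ecg_reference()].
#'
#' @param n_samples Reference length (default 512).
#' @param components Data frame with columns `center` (s, relative to the
#'   R peak), `amp` and `width` (s) for each Gaussian.
#' @param span Two-element window in seconds around the R peak.
#' @return Object of class `ecg_reference`: list with `samples` (in
#'   \[0, 1\], unique global maximum at the R wave), `n_samples` and
#'   `span`.
#' @export
ecg_reference <- function(n_samples = 512,
                          components = pqrst_components(),
                          span = c(-0.35, 0.45)) {
  t <- seq(span[1], span[2], length.out = n_samples)
  v <- gaussian_pqrst(t, components)
  structure(list(samples = normalize01(v), n_samples = n_samples,
                 span = span),
            class = "ecg_reference")
}

#' @rdname ecg_reference
#' @export
pqrst_components <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             center = c(-0.2, -0.025, 0, 0.025, 0.25),
             amp = c(0.15, -0.1, 1, -0.15, 0.3),
             width = c(0.025, 0.01, 0.01, 0.012, 0.05))
}

# sum-of-Gaussians PQRST evaluation at times t (seconds, R peak at 0)
gaussian_pqrst <- function(t, components = pqrst_components()) {
  v <- numeric(length(t))
  for (i in seq_len(nrow(components)))
    v <- v + components$amp[i] *
      exp(-((t - components$center[i])^2) / (2 * components$width[i]^2))
  v
}

#' Read an ECG reference from a one-column CSV
#'
#' @param path CSV file with a single `value` column.
#' @param span Time span in seconds covered by the samples, relative to
#'   the R peak.
#' @return An `ecg_reference`.
#' @export
read_ecg_reference <- function(path, span = c(-0.35, 0.45)) {
  v <- utils::read.csv(path)$value
  structure(list(samples = normalize01(v), n_samples = length(v),
                 span = span),
            class = "ecg_reference")
}

#' Segment the ECG channel by the PPG beat onsets
#'
#' The ECG is never segmented on its own: each segment mirrors one PPG
#' beat exactly (same index range), so the two channels stay beat-paired.
#'
#' @param ecg An ECG [sampled_signal()], sample-aligned with the PPG.
#' @param onsets PPG onset indices.
#' @param fs_ppg Sampling rate of the PPG record, used to verify alignment.
#' @return List of `ecg_segment`s: `samples`, `fs`, `onset` (record index),
#'   `applied_shift` (initially 0).
#' @export
segment_ecg_by_onsets <- function(ecg, onsets, fs_ppg = ecg$fs) {
  stopifnot(inherits(ecg, "sampled_signal"))
  if (!isTRUE(all.equal(ecg$fs, fs_ppg)))
    stop("ECG and PPG sampling rates differ; channels must be sample-aligned")
  if (length(onsets) < 2) return(list())
  lapply(seq_len(length(onsets) - 1L), function(i) {
    idx <- onsets[i]:(onsets[i + 1] - 1L)
    structure(list(samples = ecg$samples[idx], fs = ecg$fs,
                   onset = onsets[i], applied_shift = 0L),
              class = "ecg_segment")
  })
}

#' Align a segment to a reference by their peaks
#'
#' Shifts the segment so that its global maximum coincides with the
#' reference's global maximum: `delta = argmax(reference) -
#' argmax(segment)`. The shift pads with `NA` (no circular wrap-around, so
#' no fabricated correlation at the edges); downstream correlation is
#' computed on the overlapping support only.
#'
#' @param segment,reference Numeric vectors of equal length.
#' @return List with `shifted` (same length, `NA` outside the support) and
#'   `delta` (samples).
#' @export
align_to_peak <- function(segment, reference) {
  segment <- as.numeric(segment); reference <- as.numeric(reference)
  delta <- which.max(reference) - which.max(segment)
  n <- length(segment)
  shifted <- rep(NA_real_, n)
  src <- seq_len(n) - delta           # shifted[i] = segment[i - delta]
  ok <- src >= 1 & src <= n
  shifted[ok] <- segment[src[ok]]
  list(shifted = shifted, delta = delta)
}

# Pearson rho(0) on the overlapping (non-NA) support of two vectors
overlap_rho0 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("overlap too short for correlation")
  normalized_xcorr(a[ok], b[ok], mode = "pearson", lags = 0)$rho[["h0"]]
}

# Gaussian smoothing kernel applied by direct convolution (reflected
# edges); sigma in samples. Projects a wide-band waveform onto the pulse
# band before a form comparison.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  if (n < 3) return(x)
  hl <- min(half, n - 1)
  xp <- c(rev(x[2:(hl + 1)]), x, rev(x[(n - hl):(n - 1)]))
  y <- fft_convolve(xp, k)
  y[(half + hl + 1):(half + hl + n)]
}

# slice `samples` around a peak (default: global maximum) with asymmetric
# extents (seconds); extents are clamped to the available support and
# returned so the counterpart window can be cut to identical relative
# times.
peak_window <- function(samples, fs, w_left, w_right, p = which.max(samples)) {
  n <- length(samples)
  wl <- min(w_left, (p - 1) / fs)
  wr <- min(w_right, (n - p) / fs)
  idx <- (p - round(wl * fs)):(p + round(wr * fs))
  list(values = samples[idx], w_left = wl, w_right = wr)
}

# slice an ecg_reference to the window [-w_left, +w_right] seconds around
# its R peak, by interpolation on its own time axis
reference_window <- function(ecg_ref, w_left, w_right, n_out) {
  tax <- seq(ecg_ref$span[1], ecg_ref$span[2], length.out = ecg_ref$n_samples)
  t_r <- tax[which.max(ecg_ref$samples)]
  tq <- seq(t_r - w_left, t_r + w_right, length.out = n_out)
  tq <- pmin(pmax(tq, tax[1]), tax[length(tax)])
  stats::approx(tax, ecg_ref$samples, xout = tq)$y
}

#' Validate one ECG beat by the dual cross-correlation AND gate
#'
#' The "double check": the ECG segment must correlate (Pearson, lag 0)
#' at least `threshold` with *both* the first derivative of the compliant
#' PPG beat (validation as to form) and the ECG reference pattern
#' (validation as to value/content).
#'
#' Both comparisons are made on peak-centred windows cut in seconds
#' (`window` each side, clamped to the available support and mirrored
#' onto the counterpart so both slices cover identical relative times),
#' normalised to \[0, 1\] and resampled to the reference length, then
#' peak-aligned by [align_to_peak()] with the correlation taken on the
#' overlapping support. For the form check the ECG window is first
#' projected onto the configured PPG passband `band_hz` with a
#' difference-of-Gaussians kernel (each -3 dB point matching one band
#' edge): a sharp R spike and a band-limited pulse derivative can only
#' be compared as shapes at a common bandwidth. Set `sigma_form = 0` to
#' compare raw waveforms instead.
#'
#' @param ecg_seg An `ecg_segment` (or numeric vector).
#' @param ppg_beat The paired compliant `segmented_beat` (or numeric
#'   vector of PPG samples; `fs` then required).
#' @param ecg_ref An [ecg_reference()].
#' @param threshold AND-gate threshold for both scores (default 0.80).
#' @param window Half-window in seconds around each peak.
#' @param band_hz Two-element PPG passband (Hz) used to derive the
#'   form-check projection kernel.
#' @param sigma_form Plain Gaussian kernel standard deviation in seconds;
#'   overrides `band_hz` when given (`0` disables smoothing).
#' @param fs Sampling rate, needed only for bare numeric inputs.
#' @return Object of class `validation_result`: list with `rho_dppg`,
#'   `rho_ref`, `threshold` and `valid`.
#' @export
validate_ecg_beat <- function(ecg_seg, ppg_beat, ecg_ref, threshold = 0.80,
                              window = 0.3, band_hz = c(1, 3.8),
                              sigma_form = NULL, fs = NULL) {
  stopifnot(inherits(ecg_ref, "ecg_reference"))
  ns <- ecg_ref$n_samples
  seg_samples <- if (inherits(ecg_seg, "ecg_segment")) ecg_seg$samples else as.numeric(ecg_seg)
  if (is.null(fs))
    fs <- if (inherits(ecg_seg, "ecg_segment")) ecg_seg$fs
          else if (inherits(ppg_beat, "segmented_beat")) ppg_beat$fs
          else stop("'fs' required for bare numeric inputs")
  ppg_samples <- if (inherits(ppg_beat, "segmented_beat")) ppg_beat$samples else as.numeric(ppg_beat)
  dppg <- first_derivative(ppg_samples, fs = fs)$samples

  # --- form check: ECG (pulse-band projected) vs dPPG, peak-aligned.
  # The dPPG anchor is the maximum slope of the systolic upstroke, which
  # by the min-to-min segmentation convention lies in the leading third
  # of the beat. The ECG anchor is the dominant pulse-band feature of the
  # *same cardiac cycle*: with the R wave leading the pulse onset by the
  # arrival delay, that feature (the repolarisation ridge) lies in the
  # segment's leading quarter second - restricting the search there keeps
  # the next cycle's complex at the segment end from capturing the window.
  seg_form <- if (!is.null(sigma_form)) {
    gauss_smooth(seg_samples, sigma_form * fs)
  } else {
    s_lp <- sqrt(2 * log(2)) / (2 * pi * band_hz[2])
    s_hp <- sqrt(2 * log(2)) / (2 * pi * band_hz[1])
    gauss_smooth(seg_samples, s_lp * fs) - gauss_smooth(seg_samples, s_hp * fs)
  }
  up_reg <- max(3L, round(0.35 * length(dppg)))
  d_anchor <- which.max(dppg[seq_len(up_reg)])
  f_reg <- seq_len(max(3L, min(length(seg_form), round(0.25 * fs))))
  f_anchor <- f_reg[which.max(seg_form[f_reg])]
  we <- peak_window(seg_form, fs, window, window, p = f_anchor)
  wd <- peak_window(dppg, fs, window, window, p = d_anchor)
  wl <- min(we$w_left, wd$w_left); wr <- min(we$w_right, wd$w_right)
  a <- normalize01(rescale_to(peak_window(seg_form, fs, wl, wr, p = f_anchor)$values, ns))
  b <- normalize01(rescale_to(peak_window(dppg, fs, wl, wr, p = d_anchor)$values, ns))
  al <- align_to_peak(a, b)
  rho_dppg <- overlap_rho0(al$shifted, b)

  # --- content check: raw ECG vs reference PQRST, peak-centred
  we <- peak_window(seg_samples, fs, window, window)
  wl <- min(we$w_left, -ecg_ref$span[1]); wr <- min(we$w_right, ecg_ref$span[2])
  a <- normalize01(rescale_to(peak_window(seg_samples, fs, wl, wr)$values, ns))
  r <- normalize01(reference_window(ecg_ref, wl, wr, ns))
  al <- align_to_peak(a, r)
  rho_ref <- overlap_rho0(al$shifted, r)

  structure(list(rho_dppg = rho_dppg, rho_ref = rho_ref,
                 threshold = threshold,
                 valid = rho_dppg >= threshold && rho_ref >= threshold),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> rho_dppg = %.4f, rho_ref = %.4f (>= %.2f): %s\n",
              x$rho_dppg, x$rho_ref, x$threshold,
              if (x$valid) "valid" else "rejected"))
  invisible(x)
}

#' Run the full PPG + ECG screening over one paired record
#'
#' Pre-filters both channels, segments the PPG by first-derivative
#' analysis, scores every beat against the template, and - for compliant
#' PPG beats only - validates the paired ECG segment through the
#' AND gate. With `ecg = NULL` the ECG stage is skipped.
#'
#' @param ppg,ecg Paired [sampled_signal()]s (equal rate and origin);
#'   `ecg` may be `NULL`.
#' @param template A `ppg_template` (defaults to the built-in
#'   reaction-diffusion template).
#' @param ecg_ref An [ecg_reference()].
#' @param config A [pipeline_config()]; thresholds, filter specs and
#'   segmentation guards are taken from it.
#' @return List with `onsets`, `beats`, `scored` (data frame from
#'   [classify_beats()]) and `validation` (data frame, one row per
#'   compliant beat with `start`, `rho_dppg`, `rho_ref`, `valid`).
#' @export
validate_record <- function(ppg, ecg = NULL, template = NULL,
                            ecg_ref = ecg_reference(),
                            config = pipeline_config(fs = ppg$fs)) {
  if (is.null(template)) template <- default_template(config$n_samples)
  ppg_f <- ppg_bandpass(ppg, config$ppg_filter)
  onsets <- detect_onsets(ppg_f, config$refractory, config$prominence_frac)
  beats <- segment_beats(ppg_f, onsets, min_duration = config$min_beat_duration)
  scored <- classify_beats(beats, template, config$ppg_threshold,
                           config$correlation_mode, config$strict_all_lags)

  validation <- data.frame(start = integer(0), rho_dppg = numeric(0),
                           rho_ref = numeric(0), valid = logical(0))
  if (!is.null(ecg)) {
    ecg_f <- ecg_bandpass(ecg, config$ecg_filter)
    segs <- segment_ecg_by_onsets(ecg_f, onsets, ppg$fs)
    # beats can be filtered by min_duration; map back by start index
    seg_starts <- vapply(segs, function(s) s$onset, 0L)
    keep <- which(scored$compliant)
    rows <- lapply(keep, function(i) {
      j <- match(scored$start[i], seg_starts)
      vr <- if (is.na(j)) NULL else tryCatch(
        validate_ecg_beat(segs[[j]], beats[[i]], ecg_ref, config$ecg_threshold,
                          band_hz = c(config$ppg_filter$highpass$f_pass,
                                      config$ppg_filter$lowpass$f_pass)),
        error = function(e) NULL)
      if (is.null(vr))
        data.frame(start = scored$start[i], rho_dppg = NA_real_,
                   rho_ref = NA_real_, valid = FALSE)
      else
        data.frame(start = scored$start[i], rho_dppg = vr$rho_dppg,
                   rho_ref = vr$rho_ref, valid = vr$valid)
    })
    if (length(rows)) validation <- do.call(rbind, rows)
  }
  list(onsets = onsets, beats = beats, scored = scored, validation = validation)
}
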