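#' First derivative of a signal
#'
#' Central differences scaled by the sampling rate (units: input units per
#' second); one-sided differences at the endpoints.
#'
#' @param signal A [sampled_signal()] (or numeric vector with `fs` given).
#' @param fs Sampling rate, required when `signal` is a bare vector.
#' @return A [sampled_signal()] of the same length.
#' @export
first_derivative <- function(signal, fs = NULL) {
  if (!inherits(signal, "sampled_signal")) signal <- sampled_signal(signal, fs)
  x <- signal$samples
  n <- length(x)
  if (n < 3) stop("signal too short for differentiation (need >= 3 samples)")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  sampled_signal(d * signal$fs, signal$fs, signal$t0,
                 paste0("d/dt ", signal$label))
}

# centred moving average with reflected edges; w <= 1 is a no-op
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  half <- floor(w / 2)
  w <- 2 * half + 1
  xp <- c(rev(x[2:(half + 1)]), x, rev(x[(length(x) - half):(length(x) - 1)]))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}

#' Detect beat onsets by first-derivative analysis
#'
#' Beat onsets are the local minima of the pulse waveform: indices where
#' the first derivative crosses zero from negative to positive. Two guards
#' make the raw crossing rule usable on noisy signals: a prominence floor
#' (the signal must rise by at least `prominence_frac` of the record's
#' interquartile amplitude within the look-ahead window following the
#' candidate) and a refractory period (no two onsets closer than
#' `refractory` seconds). When several candidates compete within one
#' refractory window the *deepest* minimum wins - the beat onset is the
#' waveform's true trough, and artifact-induced shallow dips nearby must
#' not displace it.
#'
#' @param ppg A filtered PPG [sampled_signal()].
#' @param refractory Minimum onset spacing in seconds (default 0.3 s,
#'   i.e. at most 200 beats/min).
#' @param prominence_frac Rise threshold as a fraction of the record IQR.
#' @return Strictly increasing integer vector of onset indices (1-based);
#'   may be empty.
#' @export
detect_onsets <- function(ppg, refractory = 0.3, prominence_frac = 0.1) {
  stopifnot(inherits(ppg, "sampled_signal"))
  x <- ppg$samples
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- first_derivative(ppg)$samples
  cand <- which(d[-n] < 0 & d[-1] >= 0) + 1L   # - -> + crossings
  if (!length(cand)) return(integer(0))
  floor_amp <- prominence_frac * stats::IQR(x)
  look <- max(1L, round(refractory * ppg$fs))
  refr <- refractory * ppg$fs
  rise <- vapply(cand, function(k) max(x[k:min(n, k + look)]) - x[k], 0)
  cand <- cand[rise >= floor_amp]
  if (!length(cand)) return(integer(0))
  # resolve refractory conflicts in favour of the deepest trough:
  # repeatedly accept the globally deepest remaining candidate and drop
  # its neighbours within the refractory window
  ord <- cand[order(x[cand], cand)]
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) || all(abs(accepted - k) >= refr))
      accepted <- c(accepted, k)
  }
  sort(accepted)
}

#' Slice a record into beats
#'
#' One beat per consecutive onset pair, half-open `[onset, next_onset)`:
#' beat `i` holds samples `onsets[i] .. onsets[i+1] - 1`. Partial data
#' before the first and after the last onset is discarded.
#'
#' @param ppg A [sampled_signal()].
#' @param onsets Sorted onset indices from [detect_onsets()].
#' @param locate Also run [locate_fiducials()] on each beat.
#' @param min_duration Minimum beat duration in seconds; shorter slices are
#'   dropped.
#' @return List of `segmented_beat` objects (possibly empty): each has
#'   `samples`, `fs`, `start_index` (position in the source record) and
#'   `fiducials`.
#' @export
segment_beats <- function(ppg, onsets, locate = TRUE, min_duration = 0.25) {
  stopifnot(inherits(ppg, "sampled_signal"))
  if (is.unsorted(onsets, strictly = TRUE)) stop("'onsets' must be strictly increasing")
  if (length(onsets) < 2) return(list())
  beats <- vector("list", length(onsets) - 1L)
  for (i in seq_len(length(onsets) - 1L)) {
    idx <- onsets[i]:(onsets[i + 1] - 1L)
    beat <- structure(list(samples = ppg$samples[idx], fs = ppg$fs,
                           start_index = onsets[i], fiducials = NULL),
                      class = "segmented_beat")
    beats[[i]] <- beat
  }
  beats <- Filter(function(b) length(b$samples) >= min_duration * ppg$fs, beats)
  if (locate) beats <- lapply(beats, function(b) {
    b$fiducials <- locate_fiducials(b)
    b
  })
  beats
}

#' @export
print.segmented_beat <- function(x, ...) {
  cat(sprintf("<segmented_beat> %d samples @ %g Hz, start %d\n",
              length(x$samples), x$fs, x$start_index))
  invisible(x)
}

#' Locate fiducial points within one beat
#'
#' The systolic peak is the beat's global maximum. The dicrotic notch is
#' the first local minimum after the systolic peak and the diastolic peak
#' the first local maximum after the notch, both found on a lightly
#' smoothed copy of the beat (centred moving average, `smooth_ms`
#' milliseconds; set to 0 for an exact extrema scan). When no local
#' minimum follows the peak the notch falls back to the strongest
#' concave-up inflection of the second derivative; fields that cannot be
#' found are `NA`.
#'
#' @param beat A `segmented_beat`.
#' @param smooth_ms Moving-average window for notch/diastolic detection.
#' @return List `fiducial_set` with indices (into the beat, 1-based):
#'   `onset`, `systolic_peak`, `dicrotic_notch`, `diastolic_peak`, `end`.
#' @export
locate_fiducials <- function(beat, smooth_ms = 25) {
  stopifnot(inherits(beat, "segmented_beat"))
  s <- beat$samples
  n <- length(s)
  sys <- which.max(s)
  notch <- NA_integer_; dias <- NA_integer_
  if (sys < n - 1) {
    ss <- smooth_ma(s, round(smooth_ms / 1000 * beat$fs))
    d <- diff(ss)
    # first - -> + crossing of the smoothed derivative after the peak
    reg <- sys:(n - 1)
    k <- reg[which(d[utils::head(reg, -1)] < 0 & d[utils::head(reg, -1) + 1] >= 0)]
    if (length(k)) {
      notch <- k[1] + 1L
    } else {
      # fallback: strongest concave-up inflection of the second derivative
      d2 <- diff(ss, differences = 2)
      reg2 <- sys:(n - 2)
      if (length(reg2) > 1) {
        cnd <- reg2[which.max(d2[reg2])]
        if (d2[cnd] > 0) notch <- cnd + 1L
      }
    }
    if (!is.na(notch) && notch < n - 1) {
      reg <- notch:(n - 1)
      k <- reg[which(d[utils::head(reg, -1)] > 0 & d[utils::head(reg, -1) + 1] <= 0)]
      if (length(k)) dias <- k[1] + 1L
    }
  }
  structure(list(onset = 1L, systolic_peak = sys, dicrotic_notch = notch,
                 diastolic_peak = dias, end = n),
            class = "fiducial_set")
}

#' Export beats and fiducials as a data frame
#'
#' @param beats List of `segmented_beat`s from [segment_beats()].
#' @return Data frame with one row per beat: `start`, `end` (record
#'   indices) and the fiducial indices relative to the record.
#' @export
beats_table <- function(beats) {
  if (!length(beats))
    return(data.frame(start = integer(0), end = integer(0),
                      systolic_peak = integer(0), dicrotic_notch = integer(0),
                      diastolic_peak = integer(0)))
  do.call(rbind, lapply(beats, function(b) {
    f <- if (is.null(b$fiducials)) locate_fiducials(b) else b$fiducials
    off <- b$start_index - 1L
    data.frame(start = b$start_index,
               end = b$start_index + length(b$samples) - 1L,
               systolic_peak = f$systolic_peak + off,
               dicrotic_notch = f$dicrotic_notch + off,
               diastolic_peak = f$diastolic_peak + off)
  }))
}
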