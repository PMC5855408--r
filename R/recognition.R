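#' Min-max normalisation to \[0, 1\]
#'
#' @param samples Numeric vector with non-zero dynamic range.
#' @return `(x - min) / (max - min)`.
#' @export
normalize01 <- function(samples) {
  samples <- as.numeric(samples)
  rng <- range(samples)
  if (rng[1] == rng[2]) stop("cannot normalise a constant sequence (zero dynamic range)")
  (samples - rng[1]) / (rng[2] - rng[1])
}

#' Resample a sequence to a fixed length
#'
#' Interpolates to exactly `n_samples` points over the same support,
#' preserving the endpoints: cubic (natural spline) when the input has at
#' least 4 points, linear otherwise.
#'
#' @param samples Numeric vector (length >= 2).
#' @param n_samples Target length (>= 2).
#' @return Numeric vector of length `n_samples`.
#' @export
rescale_to <- function(samples, n_samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to rescale")
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (n == n_samples) return(samples)
  xout <- seq(1, n, length.out = n_samples)
  if (n >= 4) stats::spline(seq_len(n), samples, xout = xout, method = "natural")$y
  else stats::approx(seq_len(n), samples, xout = xout)$y
}

#' Lagged sample cross-covariance
#'
#' For sequences of common length Ns and lag h,
#' \deqn{\gamma_{12}(h) = \frac{1}{N_s} \sum_{k=1}^{N_s-h}
#'   (p_1(k) - \mu_1)(p_2(k+h) - \mu_2)}
#' with full-length sample means; note the 1/Ns scaling regardless of lag.
#'
#' @param p1,p2 Numeric vectors of equal length.
#' @param h Non-negative integer lag, `h < length(p1)`.
#' @return The scalar cross-covariance.
#' @export
sample_xcov <- function(p1, p2, h = 0) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  ns <- length(p1)
  if (length(p2) != ns) stop("'p1' and 'p2' must have equal length")
  if (h < 0 || h >= ns) stop("lag 'h' must satisfy 0 <= h < length(p1)")
  k <- seq_len(ns - h)
  sum((p1[k] - mean(p1)) * (p2[k + h] - mean(p2))) / ns
}

#' Lagged normalised cross-correlation score
#'
#' Computes the per-lag scores over lags `h = 0, 1, 2` and their mean.
#' In `"pearson"` mode (the default) the normaliser is
#' `sqrt(gamma11(0) * gamma22(0))`, so identical inputs score exactly 1;
#' `"as_printed"` retains the typeset form `gamma11(0) * gamma22(0)`
#' (no square root) for fidelity checks against the published formula.
#'
#' @param p1,p2 Numeric vectors of equal length, non-constant.
#' @param mode `"pearson"` or `"as_printed"`.
#' @param lags Integer lags scored (default `0:2`).
#' @return An object of class `xcorr_result`: list with `gamma`, `rho`
#'   (named by lag), `mean_rho` and `mode`.
#' @export
normalized_xcorr <- function(p1, p2, mode = c("pearson", "as_printed"),
                             lags = 0:2) {
  mode <- match.arg(mode)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p2) != length(p1)) stop("'p1' and 'p2' must have equal length")
  g11 <- sample_xcov(p1, p1, 0)
  g22 <- sample_xcov(p2, p2, 0)
  if (g11 <= 0 || g22 <= 0) stop("zero variance input: correlation undefined")
  gam <- vapply(lags, function(h) sample_xcov(p1, p2, h), 0)
  denom <- if (mode == "pearson") sqrt(g11 * g22) else g11 * g22
  rho <- gam / denom
  names(gam) <- names(rho) <- paste0("h", lags)
  structure(list(gamma = gam, rho = rho, mean_rho = mean(rho), mode = mode),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> mode=%s  rho(h): %s  mean = %.4f\n", x$mode,
              paste(sprintf("%.4f", x$rho), collapse = ", "), x$mean_rho))
  invisible(x)
}

#' Score one beat against the reference template
#'
#' The beat is resampled to the template length Ns, min-max normalised to
#' \[0, 1\] and scored by [normalized_xcorr()] against the template; it is
#' compliant when the lag-averaged score reaches the threshold (published
#' rule: mean over lags 0..2 at least 0.90). `strict_all_lags = TRUE`
#' instead requires every per-lag score to reach the threshold.
#'
#' @param beat A `segmented_beat` (or numeric vector of beat samples).
#' @param template A `ppg_template`.
#' @param threshold Compliance threshold (default 0.90).
#' @param mode Correlation mode, see [normalized_xcorr()].
#' @param strict_all_lags Require all lags (not just the mean) to pass.
#' @return An object of class `scored_beat`: list with `beat`, `score`
#'   (an `xcorr_result`), `compliant` and `threshold_used`.
#' @export
classify_beat <- function(beat, template, threshold = 0.90,
                          mode = c("pearson", "as_printed"),
                          strict_all_lags = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(template, "ppg_template"))
  samples <- if (inherits(beat, "segmented_beat")) beat$samples else as.numeric(beat)
  p1 <- normalize01(rescale_to(samples, template$n_samples))
  score <- normalized_xcorr(p1, template$samples, mode = mode)
  ok <- if (strict_all_lags) all(score$rho >= threshold) else score$mean_rho >= threshold
  structure(list(beat = beat, score = score, compliant = ok,
                 threshold_used = threshold),
            class = "scored_beat")
}

#' @export
print.scored_beat <- function(x, ...) {
  cat(sprintf("<scored_beat> mean_rho = %.4f (threshold %.2f): %s\n",
              x$score$mean_rho, x$threshold_used,
              if (x$compliant) "compliant" else "rejected"))
  invisible(x)
}

#' Score a list of beats
#'
#' Applies [classify_beat()] to each beat; beats whose score is undefined
#' (e.g. zero dynamic range after a sensor dropout) are marked
#' non-compliant with `NA` scores instead of failing.
#'
#' @inheritParams classify_beat
#' @param beats List of `segmented_beat`s.
#' @return Data frame with one row per beat: `start`, `end`, `rho0`,
#'   `rho1`, `rho2`, `mean_rho`, `compliant`.
#' @export
classify_beats <- function(beats, template, threshold = 0.90,
                           mode = c("pearson", "as_printed"),
                           strict_all_lags = FALSE) {
  mode <- match.arg(mode)
  rows <- lapply(beats, function(b) {
    sb <- tryCatch(classify_beat(b, template, threshold, mode, strict_all_lags),
                   error = function(e) NULL)
    start <- if (inherits(b, "segmented_beat")) b$start_index else NA_integer_
    len <- if (inherits(b, "segmented_beat")) length(b$samples) else length(b)
    if (is.null(sb))
      data.frame(start = start, end = start + len - 1L, rho0 = NA_real_,
                 rho1 = NA_real_, rho2 = NA_real_, mean_rho = NA_real_,
                 compliant = FALSE)
    else
      data.frame(start = start, end = start + len - 1L,
                 rho0 = sb$score$rho[["h0"]], rho1 = sb$score$rho[["h1"]],
                 rho2 = sb$score$rho[["h2"]], mean_rho = sb$score$mean_rho,
                 compliant = sb$compliant)
  })
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0), rho0 = numeric(0),
                      rho1 = numeric(0), rho2 = numeric(0),
                      mean_rho = numeric(0), compliant = logical(0)))
  do.call(rbind, rows)
}
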