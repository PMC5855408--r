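#' Uniformly sampled signal
#'
#' Container for one uniformly sampled real-valued channel. All pipeline
#' stages consume and return `sampled_signal` objects so that the sampling
#' rate and time origin travel with the data.
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param label Optional channel label (e.g. `"ppg"`, `"ecg"`).
#'
#' @return An object of class `sampled_signal`: a list with elements
#'   `samples`, `fs`, `t0` and `label`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 2 * (0:999) / 1000), fs = 1000)
#' s
#' @export
sampled_signal <- function(samples, fs, t0 = 0, label = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("signal contains NA or non-finite samples")
  structure(list(samples = samples, fs = fs, t0 = t0, label = label),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s: %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Sample times of a signal
#'
#' @param x A [sampled_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

as_sampled_signal <- function(x, fs, label = "") {
  if (inherits(x, "sampled_signal")) x else sampled_signal(x, fs, label = label)
}
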