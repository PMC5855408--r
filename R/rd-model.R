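#' Piecewise-linear saturation output
#'
#' The cell output nonlinearity `y = (|x + 1| - |x - 1|) / 2`: identity on
#' \[-1, 1\], saturating at -1 and +1 outside.
#'
#' @param x Numeric vector (finite).
#' @return Numeric vector of the same length, bounded in \[-1, 1\].
#' @examples
#' pwl_output(c(-3, -0.5, 0, 0.08, 2))
#' @export
pwl_output <- function(x) {
  0.5 * (abs(x + 1) - abs(x - 1))
}

#' Parameters of the two-cell reaction-diffusion oscillator
#'
#' The published parameter set (`mu = 0.5`, `rho1 = -0.3`, `rho2 = 0.3`,
#' `beta = 1`, `x1(0) = 0.1`, `x2(0) = 0.08`) drives the second state
#' variable onto a stable limit cycle whose single period closely resembles
#' a PPG pulse (systolic upstroke, dicrotic notch, diastolic runoff).
#'
#' @param mu,rho1,rho2,beta Dimensionless model parameters.
#' @param x1_0,x2_0 Initial states.
#' @return An object of class `rd_params`.
#' @export
rd_params <- function(mu = 0.5, rho1 = -0.3, rho2 = 0.3, beta = 1,
                      x1_0 = 0.1, x2_0 = 0.08) {
  vals <- c(mu = mu, rho1 = rho1, rho2 = rho2, beta = beta,
            x1_0 = x1_0, x2_0 = x2_0)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  structure(as.list(vals), class = "rd_params")
}

rd_rhs <- function(t, y, p) {
  y1 <- pwl_output(y[1]); y2 <- pwl_output(y[2])
  list(c(-y[1] + (1 + p$mu) * y1 - p$beta * y2 + p$rho1,
         -y[2] + (1 + p$mu) * y2 + p$beta * y1 + p$rho2))
}

#' Integrate the reaction-diffusion oscillator
#'
#' Fixed-step fourth-order Runge-Kutta integration of the two coupled
#' cells
#' \deqn{dx_1/dt = -x_1 + (1+\mu) y_1 - \beta y_2 + \rho_1}
#' \deqn{dx_2/dt = -x_2 + (1+\mu) y_2 + \beta y_1 + \rho_2}
#' with the saturation outputs \eqn{y_j = (|x_j+1| - |x_j-1|)/2}.
#'
#' @param params An [rd_params()] object.
#' @param t_end Final time (model time units).
#' @param dt Fixed integration step.
#' @param method Integration method passed to [deSolve::ode()]; the fixed
#'   step RK4 default keeps runs bit-reproducible across platforms.
#' @return An object of class `rd_trajectory`: list with `t`, `x1`, `x2`,
#'   `dt`.
#' @export
integrate_rd <- function(params = rd_params(), t_end = 100, dt = 1e-3,
                         method = "rk4") {
  stopifnot(inherits(params, "rd_params"), t_end > 0, dt > 0)
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(c(params$x1_0, params$x2_0), times, rd_rhs, params,
                      method = method)
  x1 <- out[, 2]; x2 <- out[, 3]
  if (any(!is.finite(x1)) || any(!is.finite(x2))) {
    bad <- which(!is.finite(x1) | !is.finite(x2))[1]
    stop(sprintf("non-finite state at t = %g", out[bad, 1]))
  }
  structure(list(t = out[, 1], x1 = x1, x2 = x2, dt = dt),
            class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf("<rd_trajectory> %d steps, dt = %g, t in [0, %g]\n",
              length(x$t), x$dt, max(x$t)))
  invisible(x)
}

# upward crossing times of (x - level), linearly interpolated
upward_crossings <- function(t, x, level) {
  s <- x - level
  k <- which(s[-length(s)] < 0 & s[-1] >= 0)
  t[k] + (t[k + 1] - t[k]) * (-s[k]) / (s[k + 1] - s[k])
}

#' Extract the PPG reference template from a trajectory
#'
#' Discards the transient, detects the steady oscillation of `x2`, slices
#' one period between two consecutive waveform minima (matching the
#' min-to-min beat segmentation convention), min-max normalises it to
#' \[0, 1\] and resamples it to `n_samples` points by cubic-spline
#' interpolation.
#'
#' @param traj An `rd_trajectory` from [integrate_rd()].
#' @param n_samples Template length Ns (default 512).
#' @param transient Time discarded at the start (model units).
#' @param min_ptp Minimum post-transient peak-to-peak amplitude below which
#'   the trajectory is declared non-oscillating.
#' @return An object of class `ppg_template`: list with `samples` (in
#'   \[0, 1\], `min = 0`, `max = 1`), `n_samples` and `period` (model time
#'   units of the source oscillation).
#' @export
extract_template <- function(traj, n_samples = 512, transient = 30,
                             min_ptp = 1e-3) {
  stopifnot(inherits(traj, "rd_trajectory"), n_samples >= 8)
  keep <- traj$t >= transient
  x <- traj$x2[keep]; t <- traj$t[keep]
  if (diff(range(x)) < min_ptp)
    stop("no oscillation detected after the transient (peak-to-peak below tolerance)")
  mid <- (min(x) + max(x)) / 2
  ct <- upward_crossings(t, x, mid)
  if (length(ct) < 4)
    stop("trajectory too short: need at least 3 full periods after the transient")
  # minima indices between consecutive mid-level upward crossings
  min_idx <- vapply(seq_len(length(ct) - 1), function(i) {
    w <- which(t >= ct[i] & t < ct[i + 1])
    w[which.min(x[w])]
  }, 0L)
  # use the penultimate full period (well inside the limit cycle)
  i0 <- min_idx[length(min_idx) - 1L]
  i1 <- min_idx[length(min_idx)]
  slice <- x[i0:i1]
  period <- t[i1] - t[i0]
  res <- rescale_to(slice, n_samples)
  structure(list(samples = normalize01(res), n_samples = n_samples,
                 period = period),
            class = "ppg_template")
}

#' @export
print.ppg_template <- function(x, ...) {
  cat(sprintf("<ppg_template> Ns = %d, source period = %.5f time units\n",
              x$n_samples, x$period))
  invisible(x)
}

#' Measure the oscillation period of a trajectory
#'
#' Mean spacing of successive upward mid-level crossings of `x2` after the
#' transient (crossing times linearly interpolated between samples).
#'
#' @inheritParams extract_template
#' @return Period in model time units.
#' @export
rd_period <- function(traj, transient = 30) {
  keep <- traj$t >= transient
  x <- traj$x2[keep]; t <- traj$t[keep]
  ct <- upward_crossings(t, x, (min(x) + max(x)) / 2)
  if (length(ct) < 2) stop("fewer than two oscillation periods after the transient")
  mean(diff(ct))
}

#' Write / read a template as plain text
#'
#' One sample per row, CSV with a `value` header; metadata (Ns, period) in
#' a JSON side-car when `meta_path` is given.
#'
#' @param template A `ppg_template`.
#' @param path CSV output path.
#' @param meta_path Optional JSON metadata path.
#' @export
write_template <- function(template, path, meta_path = NULL) {
  stopifnot(inherits(template, "ppg_template"))
  utils::write.csv(data.frame(value = template$samples), path, row.names = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(list(n_samples = template$n_samples,
                              period = template$period),
                         meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @return `read_template` returns a `ppg_template` (period `NA` when no
#'   metadata is available).
#' @export
read_template <- function(path, meta_path = NULL) {
  v <- utils::read.csv(path)$value
  period <- NA_real_
  if (!is.null(meta_path)) period <- jsonlite::read_json(meta_path)$period
  structure(list(samples = normalize01(v), n_samples = length(v),
                 period = period),
            class = "ppg_template")
}
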