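#' State-Controlled Cellular Neural Network configuration
#'
#' An M x N grid of first-order cells with piecewise-linear outputs,
#' coupled through space-invariant cloning templates. Cell `(i, j)` obeys
#' \deqn{C \, dx_{ij}/dt = -x_{ij}/R_x + \sum A \, y_{kl} + \sum B \, u_{kl}
#'   + \sum C_t \, x_{kl} + I}
#' with sums over the radius-`r` neighbourhood, `y = pwl_output(x)`, and
#' out-of-grid neighbours contributing zero (fixed-zero boundary).
#'
#' @param M,N Grid rows and columns.
#' @param r Neighbourhood radius.
#' @param A Feedback (output-coupling) template, a `(2r+1) x (2r+1)` matrix.
#' @param B Input-coupling template, same shape.
#' @param C_t State-coupling template (the "state-controlled" extension),
#'   same shape.
#' @param I Bias: scalar, or an `M x N` matrix for space-variant bias.
#' @param R_x,C_cap Cell resistance- and capacitance-like constants.
#' @param x0 Initial state matrix (`M x N`).
#' @param u Input matrix (`M x N`).
#' @return An object of class `sccnn_config`.
#' @export
sccnn_config <- function(M, N, r = 1,
                         A = matrix(0, 2 * r + 1, 2 * r + 1),
                         B = matrix(0, 2 * r + 1, 2 * r + 1),
                         C_t = matrix(0, 2 * r + 1, 2 * r + 1),
                         I = 0, R_x = 1, C_cap = 1,
                         x0 = matrix(0, M, N), u = matrix(0, M, N)) {
  stopifnot(M >= 1, N >= 1, r >= 0)
  side <- 2 * r + 1
  for (tmpl in list(A, B, C_t))
    if (!all(dim(tmpl) == c(side, side)))
      stop(sprintf("templates must be %d x %d for radius %d", side, side, r))
  if (is.matrix(I)) stopifnot(all(dim(I) == c(M, N))) else I <- matrix(I, M, N)
  stopifnot(all(dim(x0) == c(M, N)), all(dim(u) == c(M, N)),
            R_x > 0, C_cap > 0)
  structure(list(M = M, N = N, r = r, A = A, B = B, C_t = C_t, I = I,
                 R_x = R_x, C_cap = C_cap, x0 = x0, u = u),
            class = "sccnn_config")
}

# neighbourhood sum: for each cell, sum of template-weighted neighbours.
# `field` is an M x N matrix; zero (fixed) boundary.
template_sum <- function(field, tmpl, r) {
  M <- nrow(field); N <- ncol(field)
  out <- matrix(0, M, N)
  for (di in -r:r) for (dj in -r:r) {
    w <- tmpl[di + r + 1, dj + r + 1]
    if (w == 0) next
    si <- (1:M) + di; sj <- (1:N) + dj
    vi <- si >= 1 & si <= M; vj <- sj >= 1 & sj <= N
    out[vi, vj] <- out[vi, vj] + w * field[si[vi], sj[vj], drop = FALSE]
  }
  out
}

#' Simulate a State-Controlled CNN
#'
#' Fixed-step RK4 integration of the full grid state equation (same
#' integrator and step as [integrate_rd()], so that an exactly mapped
#' two-cell network reproduces the reaction-diffusion trajectories to
#' machine precision).
#'
#' @param config An [sccnn_config()].
#' @param t_end Final time.
#' @param dt Fixed step.
#' @param method [deSolve::ode()] method.
#' @return List with `t` (times) and `x`, a `length(t) x (M*N)` matrix of
#'   states in column-major (R matrix) cell order.
#' @export
simulate_sccnn <- function(config, t_end = 100, dt = 1e-3, method = "rk4") {
  stopifnot(inherits(config, "sccnn_config"), t_end > 0, dt > 0)
  M <- config$M; N <- config$N; r <- config$r
  Bu <- template_sum(config$u, config$B, r)   # input term is constant
  rhs <- function(t, y, p) {
    x <- matrix(y, M, N)
    yout <- pwl_output(x)
    dx <- (-x / config$R_x +
             template_sum(yout, config$A, r) +
             Bu +
             template_sum(x, config$C_t, r) +
             config$I) / config$C_cap
    list(as.vector(dx))
  }
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(as.vector(config$x0), times, rhs, NULL, method = method)
  x <- out[, -1, drop = FALSE]
  if (any(!is.finite(x))) {
    bad <- which(rowSums(!is.finite(x)) > 0)[1]
    stop(sprintf("non-finite state at t = %g", out[bad, 1]))
  }
  list(t = out[, 1], x = unname(x))
}

#' Map the two-cell reaction-diffusion model onto a 1 x 2 SC-CNN
#'
#' Returns the 1 x 2 network whose state equation is algebraically
#' identical to the reaction-diffusion pair: feedback template
#' `[+beta, 1 + mu, -beta]` (the mirror antisymmetry makes cell 1 see
#' `-beta y_2` and cell 2 see `+beta y_1`), biases `rho_1`, `rho_2` as a
#' space-variant bias, zero input and state templates, and
#' `R_x = C_cap = 1`.
#'
#' @param params An [rd_params()].
#' @return An [sccnn_config()].
#' @export
rd_to_sccnn <- function(params = rd_params()) {
  stopifnot(inherits(params, "rd_params"))
  A <- matrix(0, 3, 3)
  A[2, 1] <- params$beta       # left neighbour weight
  A[2, 2] <- 1 + params$mu     # self feedback
  A[2, 3] <- -params$beta      # right neighbour weight
  sccnn_config(M = 1, N = 2, r = 1, A = A,
               I = matrix(c(params$rho1, params$rho2), 1, 2),
               x0 = matrix(c(params$x1_0, params$x2_0), 1, 2))
}
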