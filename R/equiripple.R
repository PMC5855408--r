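# Parks-McClellan (Remez exchange) equiripple FIR design, type I (odd
# length, even symmetry), implemented directly on the cosine-polynomial
# formulation with barycentric Lagrange interpolation. Orders of a few
# hundred taps converge in well under a second; very narrow transition
# bands are handled one level up by interpolated-FIR decomposition
# (see design_equiripple), which keeps every exchange at moderate order.

# Chebyshev approximation of `desired` with weights `weights` over the
# union of `bands` (matrix of [f_lo, f_hi] rows, normalised frequency
# 0..0.5). Returns impulse response of length n_taps (odd).
pm_remez <- function(n_taps, bands, desired, weights, density = 16,
                     max_iter = 80, tol = 1e-7) {
  stopifnot(n_taps %% 2 == 1, n_taps >= 3)
  m <- (n_taps - 1L) / 2L
  r <- m + 2L                       # alternation count for type I
  nb <- nrow(bands)
  delf <- 0.5 / (density * m)

  grid <- c(); Dg <- c(); Wg <- c(); seg_start <- c(); seg_end <- c()
  for (b in seq_len(nb)) {
    g <- seq(bands[b, 1], bands[b, 2], by = delf)
    if (g[length(g)] < bands[b, 2]) g <- c(g, bands[b, 2])
    seg_start <- c(seg_start, length(grid) + 1L)
    grid <- c(grid, g)
    seg_end <- c(seg_end, length(grid))
    Dg <- c(Dg, rep(desired[b], length(g)))
    Wg <- c(Wg, rep(weights[b], length(g)))
  }
  ng <- length(grid)
  if (r > ng) stop("frequency grid too coarse for requested order")
  xg <- cos(2 * pi * grid)

  # barycentric weights and levelled error for an extremal index set
  bary <- function(idx) {
    xe <- xg[idx]
    dmat <- outer(xe, xe, "-"); diag(dmat) <- 1
    lad <- -rowSums(log(abs(dmat)))           # log-scaled for stability
    sgn <- apply(sign(dmat), 1, prod)
    ad <- sgn * exp(lad - max(lad))
    De <- Dg[idx]; We <- Wg[idx]
    sgns <- (-1)^(seq_along(idx) - 1)
    delta <- sum(ad * De) / sum(ad * sgns / We)
    list(xe = xe, ad = ad, ye = De - sgns * delta / We, delta = delta)
  }
  evalA <- function(bb, x) {
    C <- outer(x, bb$xe, "-")
    hit <- abs(C) < 1e-13
    C[hit] <- 1
    K <- sweep(1 / C, 2, bb$ad, "*")
    K[hit] <- 0
    A <- rowSums(sweep(K, 2, bb$ye, "*")) / rowSums(K)
    ih <- which(rowSums(hit) > 0)
    if (length(ih))
      A[ih] <- bb$ye[apply(hit[ih, , drop = FALSE], 1, which.max)]
    A
  }

  ext <- round(seq(1, ng, length.out = r))
  for (it in seq_len(max_iter)) {
    bb <- bary(ext)
    E <- Wg * (evalA(bb, xg) - Dg)
    aE <- abs(E)
    # candidate extremals: per-band local maxima of |E| plus band edges
    cand <- c()
    for (b in seq_len(nb)) {
      i0 <- seg_start[b]; i1 <- seg_end[b]
      seg <- aE[i0:i1]
      loc <- if (length(seg) >= 3) which(diff(sign(diff(seg))) < 0) + 1 else integer(0)
      cand <- c(cand, i0 - 1L + unique(c(1L, loc, length(seg))))
    }
    cand <- sort(unique(cand))
    sg <- sign(E[cand])
    keep <- c(); i <- 1L
    while (i <= length(cand)) {           # merge same-sign runs, keep max
      j <- i
      while (j < length(cand) && sg[j + 1] == sg[i]) j <- j + 1L
      seg <- cand[i:j]
      keep <- c(keep, seg[which.max(aE[seg])])
      i <- j + 1L
    }
    while (length(keep) > r) {            # drop weakest endpoint extremal
      if (aE[keep[1]] <= aE[keep[length(keep)]]) keep <- keep[-1]
      else keep <- keep[-length(keep)]
    }
    if (length(keep) < r) {
      extra <- setdiff(cand, keep)
      extra <- extra[order(-aE[extra])]
      keep <- sort(c(keep, utils::head(extra, r - length(keep))))
      if (length(keep) < r) stop("Remez exchange degenerated")
    }
    conv <- (max(aE[keep]) - abs(bb$delta)) / max(aE[keep])
    done <- identical(as.integer(keep), as.integer(ext)) ||
      (is.finite(conv) && conv < tol)
    ext <- keep
    if (done) break
  }

  bb <- bary(ext)
  # impulse response from L equispaced amplitude samples (inverse real DFT)
  L <- n_taps
  Aj <- evalA(bb, cos(2 * pi * (0:m) / L))
  h <- vapply(0:(L - 1), function(k)
    (Aj[1] + 2 * sum(Aj[-1] * cos(2 * pi * (1:m) * (k - m) / L))) / L, 0)
  list(h = h, delta = bb$delta, iterations = it)
}

# dB ripple/attenuation <-> linear deviations
db_to_delta_pass <- function(rp) (10^(rp / 20) - 1) / (10^(rp / 20) + 1)
db_to_delta_stop <- function(as_db) 10^(-as_db / 20)

# Herrmann-Rabiner-Chan order estimate; df = transition width / fs
estimate_fir_order <- function(dp, ds, df) {
  l1 <- log10(dp); l2 <- log10(ds)
  Dinf <- (5.309e-3 * l1^2 + 7.114e-2 * l1 - 4.761e-1) * l2 -
    (2.66e-3 * l1^2 + 5.941e-1 * l1 + 4.278e-1)
  fk <- 11.01217 + 0.51244 * (l1 - l2)
  max(3, ceiling(Dinf / df - fk * df + 1))
}

# full linear convolution via FFT at a highly composite padded length;
# stats::convolve transforms at the raw length, which degenerates badly
# when that length has a large prime factor
fft_convolve <- function(x, y) {
  n_out <- length(x) + length(y) - 1L
  N <- stats::nextn(n_out, 2)
  z <- Re(stats::fft(stats::fft(c(x, numeric(N - length(x)))) *
                       stats::fft(c(y, numeric(N - length(y)))),
                     inverse = TRUE)) / N
  z[seq_len(n_out)]
}

# zero-stuff impulse response by factor M (for interpolated FIR)
expand_by <- function(h, M) {
  e <- numeric((length(h) - 1L) * M + 1L)
  e[seq(1L, length(e), by = M)] <- h
  e
}

check_lowpass <- function(h, f_pass, f_stop, dp, ds, fs, ngrid = 4096) {
  rp <- fir_response(h, seq(1e-6, f_pass, length.out = ngrid), fs)
  rs <- fir_response(h, seq(f_stop, fs / 2 - 1e-9, length.out = ngrid), fs)
  max(abs(rp - 1)) <= dp && max(rs) <= ds
}

# single-stage design with verification and order bump-up
design_lp_core <- function(f_pass, f_stop, dp, ds, fs, cap = 4001) {
  n <- estimate_fir_order(dp, ds, (f_stop - f_pass) / fs)
  if (n %% 2 == 0) n <- n + 1
  tries <- 0
  repeat {
    if (n > cap || tries > 25)
      stop(sprintf(
        "equiripple low-pass design infeasible (pass %g Hz, stop %g Hz, order %d)",
        f_pass, f_stop, n))
    h <- tryCatch(
      pm_remez(n, rbind(c(0, f_pass / fs), c(f_stop / fs, 0.5)),
               c(1, 0), c(ds / dp, 1))$h,
      error = function(e) NULL)
    if (!is.null(h) && check_lowpass(h, f_pass, f_stop, dp, ds, fs)) return(h)
    n <- n + 2 * max(1, round(n * 0.02)); if (n %% 2 == 0) n <- n + 1
    tries <- tries + 1
  }
}

# interpolated-FIR low-pass for narrow transition bands: equiripple model
# filter stretched by M (zero-stuffing) cascaded with an equiripple masking
# filter that removes the spectral images. The factor M is chosen by
# minimising the estimated total order.
design_lp_ifir <- function(f_pass, f_stop, dp, ds, fs) {
  cands <- NULL
  for (M in 2:max(2, floor(fs / (2 * f_stop)))) {
    if (f_stop * M >= 0.45 * fs) next
    g_stop <- fs / M - f_stop
    if (g_stop <= f_stop * 1.2) next
    nm <- estimate_fir_order(dp / 2, ds / 1.05, (f_stop - f_pass) * M / fs)
    ng <- estimate_fir_order(dp / 2, ds / 1.05, (g_stop - f_stop) / fs)
    cands <- rbind(cands, c(M, nm + ng))
  }
  if (is.null(cands)) stop("no feasible interpolated-FIR factor for this band")
  cands <- cands[order(cands[, 2]), , drop = FALSE]
  for (i in seq_len(min(4L, nrow(cands)))) {
    M <- cands[i, 1]
    g_stop <- fs / M - f_stop
    f_model <- tryCatch(design_lp_core(f_pass * M, f_stop * M, dp / 2, ds / 1.05, fs),
                        error = function(e) NULL)
    if (is.null(f_model)) next
    g <- tryCatch(design_lp_core(f_stop, g_stop, dp / 2, ds / 1.05, fs),
                  error = function(e) NULL)
    if (is.null(g)) next
    h <- fft_convolve(expand_by(f_model, M), g)
    if (check_lowpass(h, f_pass, f_stop, dp, ds, fs)) return(h)
  }
  stop("interpolated-FIR equiripple design failed for this specification")
}
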