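test_that("filter_spec enforces its invariants", {
  expect_error(filter_spec("low-pass", 10, 5, 0.01, 40, 1000), "f_pass < f_stop")
  expect_error(filter_spec("high-pass", 0.3, 1, 0.01, 40, 1000), "f_stop < f_pass")
  expect_error(filter_spec("low-pass", 0, 5, 0.01, 40, 1000), "inside")
  expect_error(filter_spec("low-pass", 10, 600, 0.01, 40, 1000), "inside")
  expect_error(filter_spec("low-pass", 3.8, 7.21, -1, 100, 1000))
})

test_that("both published PPG designs meet their specification on a dense grid", {
  specs <- default_filter_specs("ppg", 1000)
  lp <- design_equiripple(specs$lowpass)
  hp <- design_equiripple(specs$highpass)
  vlp <- verify_filter(lp)
  vhp <- verify_filter(hp)
  expect_true(vlp$meets_spec)
  expect_gte(vlp$min_atten_db, 100)
  expect_lte(vlp$max_ripple_db, 0.001)
  expect_true(vhp$meets_spec)
  expect_gte(vhp$min_atten_db, 40)
  expect_lte(vhp$max_ripple_db, 0.01)
  # gain at DC (high-pass): at least the stopband attenuation
  expect_lte(fir_response(hp, 1e-9), 10^(-40 / 20))
  # linear phase: exact even symmetry, odd length
  expect_identical(length(lp$coefficients) %% 2L, 1L)
  expect_equal(lp$coefficients, rev(lp$coefficients))
  expect_equal(hp$coefficients, rev(hp$coefficients))
})

test_that("small-order design agrees with an independent Remez implementation", {
  b_pkg <- rdppg:::pm_remez(61, rbind(c(0, 0.1), c(0.15, 0.5)), c(1, 0), c(1, 1))$h
  b_ref <- signal::remez(60, c(0, 0.2, 0.3, 1), c(1, 1, 0, 0), ftype = "bandpass")
  expect_lt(max(abs(b_pkg - b_ref)), 1e-4)
})

test_that("filtering a unit impulse returns the coefficients, time-aligned", {
  filt <- design_equiripple(default_filter_specs("ecg", 1000)$lowpass)
  L <- length(filt$coefficients)
  gd <- filt$group_delay
  n <- 3 * L
  x <- numeric(n); pos <- floor(n / 2); x[pos] <- 1
  y <- apply_filter(sampled_signal(x, 1000), filt)$samples
  expect_equal(y[(pos - gd):(pos + gd)], filt$coefficients, tolerance = 1e-10)
})

test_that("apply_filter is linear and preserves length, rate and alignment", {
  filt <- design_equiripple(default_filter_specs("ecg", 1000)$lowpass)
  set.seed(42)
  n <- 2000
  x <- stats::rnorm(n); y <- stats::rnorm(n)
  fx <- apply_filter(sampled_signal(x, 1000), filt)$samples
  fy <- apply_filter(sampled_signal(y, 1000), filt)$samples
  fxy <- apply_filter(sampled_signal(2 * x - 3 * y, 1000), filt)$samples
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-9)
  expect_length(fx, n)
  # all-zero in, all-zero out
  z <- apply_filter(sampled_signal(numeric(n), 1000), filt)$samples
  expect_equal(z, numeric(n), tolerance = 1e-12)
  # in-band sinusoid phase-aligned: cross-correlation peak at lag 0
  t <- (0:(n - 1)) / 1000
  s <- sin(2 * pi * 5 * t)
  fsig <- apply_filter(sampled_signal(s, 1000), filt)$samples
  cc <- stats::ccf(fsig, s, lag.max = 5, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  # too-short signal errors
  expect_error(apply_filter(sampled_signal(numeric(10), 1000), filt), "longer")
})

test_that("the PPG cascade passes the band and rejects DC and 50 Hz", {
  fs <- 1000
  n <- 20000
  t <- (0:(n - 1)) / fs
  inband <- sampled_signal(sin(2 * pi * 2 * t), fs)
  out <- ppg_bandpass(inband)$samples
  mid <- out[5000:15000]                     # avoid edge transients
  expect_lt(abs(max(mid) - 1), 0.01)
  expect_lt(abs(min(mid) + 1), 0.01)
  # DC offset removed to within the high-pass's specified 40 dB floor
  with_dc <- ppg_bandpass(sampled_signal(sin(2 * pi * 2 * t) + 5, fs))$samples
  expect_lt(abs(mean(with_dc[5000:15000]) - mean(mid)), 5 * 10^(-40 / 20))
  # 50 Hz residual matches the response oracle and is at least 100 dB down
  lp <- design_equiripple(default_filter_specs("ppg", fs)$lowpass)
  pl <- apply_filter(sampled_signal(sin(2 * pi * 50 * t), fs), lp)$samples
  amp50 <- max(abs(pl[5000:15000]))
  expect_lte(amp50, 1e-5)
  expect_lte(amp50, fir_response(lp, 50) * 1.5)
})

test_that("the ECG cascade keeps 10 Hz and rejects DC and 50 Hz", {
  fs <- 1000
  n <- 30000
  t <- (0:(n - 1)) / fs
  ten <- ecg_bandpass(sampled_signal(sin(2 * pi * 10 * t), fs))$samples
  expect_lt(abs(max(ten[10000:20000]) - 1), 0.01)
  dc <- ecg_bandpass(sampled_signal(rep(1, n), fs))$samples
  expect_lt(max(abs(dc[10000:20000])), 10^(-40 / 20) * 1.5)
  lp <- design_equiripple(default_filter_specs("ecg", fs)$lowpass)
  fifty <- apply_filter(sampled_signal(sin(2 * pi * 50 * t), fs), lp)$samples
  expect_lte(max(abs(fifty[10000:20000])), 10^(-60 / 20) * 1.5)
})

test_that("infeasible specifications raise an explicit error", {
  # sub-millihertz transition at 0.001 dB ripple needs an absurd order
  sp <- filter_spec("low-pass", 1.0, 1.0005, 0.0001, 120, 1000)
  expect_error(design_equiripple(sp, use_cache = FALSE), "infeasible|failed|feasible")
})
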