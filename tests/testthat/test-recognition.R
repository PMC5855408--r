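test_that("normalize01 maps to [0, 1] and is idempotent", {
  expect_identical(normalize01(c(1, 2, 3)), c(0, 0.5, 1))
  x <- normalize01(stats::rnorm(50))
  expect_identical(normalize01(x), x)
  # inverse-affine recovery: normalising a*x + b recovers normalize01(x)
  expect_equal(normalize01(3 * x + 7), x, tolerance = 1e-12)
  expect_error(normalize01(rep(2, 10)), "constant")
})

test_that("rescale_to preserves length-N identity, linearity and pulses", {
  x <- stats::rnorm(100)
  expect_equal(rescale_to(x, 100), x, tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 50)
  r2 <- rescale_to(ramp, 173)
  expect_equal(r2, seq(0, 1, length.out = 173), tolerance = 1e-8)
  expect_identical(r2[1], 0); expect_identical(r2[173], 1)
  # band-limited pulse survives down-then-up resampling
  tem <- fixture_template()$samples
  back <- rescale_to(rescale_to(tem, 128), 512)
  expect_lte(max(abs(back - tem)), 1e-2)
  expect_error(rescale_to(x, 1), "at least 2")
  expect_error(rescale_to(1, 10), "at least 2")
})

test_that("sample_xcov reproduces the printed sum exactly", {
  p <- c(0, 1, 0, 1)
  expect_identical(sample_xcov(p, p, 0), 0.25)
  set.seed(7)
  a <- stats::rnorm(16); b <- stats::rnorm(16)
  # single-term sum at the maximal lag
  h <- 15
  expect_equal(sample_xcov(a, b, h),
               (a[1] - mean(a)) * (b[16] - mean(b)) / 16, tolerance = 1e-14)
  # mean-zero orthogonal vectors
  expect_equal(sample_xcov(c(1, -1, 1, -1), c(1, 1, -1, -1), 0), 0,
               tolerance = 1e-15)
  expect_error(sample_xcov(a, b[1:4], 0), "equal length")
  expect_error(sample_xcov(a, b, 16), "lag")
})

test_that("sample_xcov agrees with the double-loop oracle on random inputs", {
  set.seed(11)
  for (i in 1:60) {
    ns <- sample(4:40, 1)
    p1 <- stats::rnorm(ns); p2 <- stats::rnorm(ns)
    h <- sample(0:(ns - 1), 1)
    expect_equal(sample_xcov(p1, p2, h), naive_xcov(p1, p2, h),
                 tolerance = 1e-12)
  }
})

test_that("normalized_xcorr identities and oracle values hold", {
  tem <- fixture_template()$samples
  r <- normalized_xcorr(tem, tem)
  expect_equal(unname(r$rho[["h0"]]), 1, tolerance = 1e-12)
  inv <- normalized_xcorr(tem, 1 - tem)
  expect_equal(unname(inv$rho[["h0"]]), -1, tolerance = 1e-12)
  # frozen example pair, both modes, against the independent oracle
  p1 <- c(0, 0.5, 1, 0.5); p2 <- c(0.1, 0.6, 0.9, 0.4)
  for (mode in c("pearson", "as_printed")) {
    r <- normalized_xcorr(p1, p2, mode = mode)
    for (h in 0:2)
      expect_equal(unname(r$rho[[paste0("h", h)]]),
                   naive_rho(p1, p2, h, mode), tolerance = 1e-12)
    expect_equal(r$mean_rho, mean(vapply(0:2, naive_rho, 0, p1 = p1, p2 = p2,
                                         mode = mode)), tolerance = 1e-12)
  }
  # pearson lag 0 equals the standard sample correlation
  expect_equal(unname(normalized_xcorr(p1, p2)$rho[["h0"]]), stats::cor(p1, p2),
               tolerance = 1e-12)
  expect_error(normalized_xcorr(rep(1, 5), 1:5), "variance")
})

test_that("pearson mode is invariant under positive affine maps; h = 0 is symmetric", {
  set.seed(5)
  p1 <- stats::rnorm(64); p2 <- stats::rnorm(64)
  r0 <- normalized_xcorr(p1, p2)$rho
  r1 <- normalized_xcorr(2.7 * p1 + 3, 0.4 * p2 - 1)$rho
  expect_equal(r0, r1, tolerance = 1e-9)
  expect_equal(unname(normalized_xcorr(p1, p2)$rho[["h0"]]),
               unname(normalized_xcorr(p2, p1)$rho[["h0"]]), tolerance = 1e-12)
})

test_that("classify_beat accepts the template and rejects its inversion", {
  tem <- fixture_template()
  self <- classify_beat(rescale_to(tem$samples, 850), tem)
  expect_true(self$compliant)
  expect_gte(self$score$mean_rho, 0.99)
  flipped <- classify_beat(1 - rescale_to(tem$samples, 850), tem)
  expect_false(flipped$compliant)
  expect_lt(flipped$score$mean_rho, 0)
})

test_that("acceptance is monotone non-increasing in noise level", {
  tem <- fixture_template()
  sigmas <- c(0.02, 0.1, 0.3, 0.8)
  rates <- vapply(sigmas, function(s) {
    set.seed(round(1000 * s))
    mean(vapply(1:50, function(i) {
      beat <- rescale_to(tem$samples, 700) + stats::rnorm(700, 0, s)
      classify_beat(beat, tem)$compliant
    }, TRUE))
  }, 0)
  expect_true(all(diff(rates) <= 0))
  # and the decision agrees with the oracle score at a fixed seed
  set.seed(99)
  beat <- rescale_to(tem$samples, 700) + stats::rnorm(700, 0, 0.1)
  got <- classify_beat(beat, tem)
  p1 <- normalize01(rescale_to(beat, 512))
  oracle_mean <- mean(vapply(0:2, naive_rho, 0, p1 = p1, p2 = tem$samples,
                             mode = "pearson"))
  expect_equal(got$score$mean_rho, oracle_mean, tolerance = 1e-12)
  expect_identical(got$compliant, oracle_mean >= 0.90)
})

test_that("classify_beats tolerates degenerate beats and keeps the table shape", {
  tem <- fixture_template()
  beats <- list(
    structure(list(samples = rescale_to(tem$samples, 800), fs = 1000,
                   start_index = 1L, fiducials = NULL), class = "segmented_beat"),
    structure(list(samples = rep(0.5, 800), fs = 1000,
                   start_index = 801L, fiducials = NULL), class = "segmented_beat"))
  tab <- classify_beats(beats, tem)
  expect_identical(nrow(tab), 2L)
  expect_true(tab$compliant[1])
  expect_false(tab$compliant[2])
  expect_true(is.na(tab$mean_rho[2]))
})
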