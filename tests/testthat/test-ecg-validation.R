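test_that("the synthetic ECG reference is a normalised single-peak PQRST", {
  ref <- ecg_reference()
  expect_identical(min(ref$samples), 0)
  expect_identical(max(ref$samples), 1)
  expect_identical(sum(ref$samples == 1), 1L)   # unique global maximum
  expect_identical(ref$n_samples, 512)
})

test_that("ECG segments mirror the PPG beat index ranges exactly", {
  fs <- 1000
  ecg <- sampled_signal(stats::rnorm(5000), fs)
  onsets <- c(101L, 1101L, 2101L, 3101L)
  segs <- segment_ecg_by_onsets(ecg, onsets)
  expect_length(segs, 3)
  for (i in 1:3) {
    expect_identical(segs[[i]]$onset, onsets[i])
    expect_identical(segs[[i]]$samples,
                     ecg$samples[onsets[i]:(onsets[i + 1] - 1L)])
  }
  expect_length(segment_ecg_by_onsets(ecg, integer(0)), 0)
  expect_error(segment_ecg_by_onsets(ecg, onsets, fs_ppg = 500), "rates differ")
})

test_that("align_to_peak recovers constructed shifts and is idempotent", {
  pulse <- exp(-((1:200) - 80)^2 / 200)
  al0 <- align_to_peak(pulse, pulse)
  expect_identical(al0$delta, 0L)
  expect_identical(al0$shifted, pulse)
  # segment pre-shifted by +k
  k <- 17
  shifted_in <- c(rep(0, k), pulse[1:(200 - k)])
  al <- align_to_peak(shifted_in, pulse)
  expect_equal(al$delta, -k)
  expect_identical(which.max(al$shifted), which.max(pulse))
  # random unimodal pair: argmaxes coincide after alignment (oracle check)
  set.seed(21)
  for (i in 1:20) {
    a <- exp(-((1:300) - sample(50:250, 1))^2 / stats::runif(1, 50, 500))
    b <- exp(-((1:300) - sample(50:250, 1))^2 / stats::runif(1, 50, 500))
    al <- align_to_peak(a, b)
    expect_identical(which.max(replace(al$shifted, is.na(al$shifted), -Inf)),
                     which.max(b))
    # aligning the aligned segment again is a no-op
    again <- align_to_peak(replace(al$shifted, is.na(al$shifted), 0), b)
    expect_identical(again$delta, 0L)
  }
})

test_that("matching ECG, reference and pulse derivative validate; mismatches fail", {
  # reference with an early R peak so every anchor region contains it
  ref <- ecg_reference(512, span = c(-0.1, 0.7))
  fs <- 512 / 0.8                      # segment sampled on the reference grid
  seg <- ref$samples
  ppg_match <- cumsum(seg) / fs        # first derivative reproduces seg
  vr <- validate_ecg_beat(seg, ppg_match, ref, sigma_form = 0, fs = fs)
  expect_gte(vr$rho_ref, 0.995)
  expect_gte(vr$rho_dppg, 0.99)
  expect_true(vr$valid)
  # anti-correlated pulse derivative: content passes, form fails, gate rejects
  vr2 <- validate_ecg_beat(seg, -ppg_match, ref, sigma_form = 0, fs = fs)
  expect_gte(vr2$rho_ref, 0.995)
  expect_lt(vr2$rho_dppg, 0.8)
  expect_false(vr2$valid)
  # white-noise segment fails both checks
  set.seed(8)
  vr3 <- validate_ecg_beat(stats::rnorm(512), ppg_match, ref,
                           sigma_form = 0, fs = fs)
  expect_false(vr3$valid)
})

test_that("the AND gate truth table holds in all four quadrants", {
  ref <- ecg_reference(512, span = c(-0.1, 0.7))
  fs <- 512 / 0.8
  seg <- ref$samples
  ppg_match <- cumsum(seg) / fs
  # (high, high): both scores near 1
  hi <- validate_ecg_beat(seg, ppg_match, ref, threshold = 0.9,
                          sigma_form = 0, fs = fs)
  expect_true(hi$valid)
  # (low, high) via a threshold between the two observed scores
  vr <- validate_ecg_beat(seg, -ppg_match, ref, sigma_form = 0, fs = fs)
  thr_mid <- (vr$rho_dppg + vr$rho_ref) / 2
  mid <- validate_ecg_beat(seg, -ppg_match, ref, threshold = thr_mid,
                           sigma_form = 0, fs = fs)
  expect_false(mid$valid)                       # rho_dppg < thr <= rho_ref
  # (high, high) again at a threshold below both
  lo <- validate_ecg_beat(seg, -ppg_match, ref, threshold = vr$rho_dppg - 0.05,
                          sigma_form = 0, fs = fs)
  expect_true(lo$valid)
  # (low, low) at a threshold above both
  above <- validate_ecg_beat(seg, ppg_match, ref, threshold = 1 + 1e-9,
                             sigma_form = 0, fs = fs)
  expect_false(above$valid)
  # invariant: valid <=> both scores reach the threshold
  for (v in list(hi, mid, lo, above))
    expect_identical(v$valid, v$rho_dppg >= v$threshold & v$rho_ref >= v$threshold)
})

test_that("a clean noise-free paired record is fully compliant and valid", {
  cfg <- synth_config(n_beats = 12, artifact_fraction = 0, noise_sd = 0,
                      powerline_amp = 0, baseline_wander = c(0, 0.25),
                      hr_jitter = 0, amplitude_jitter = 0, seed = 2)
  rec <- make_paired_dataset(cfg)
  res <- validate_record(rec$ppg, rec$ecg, config = pipeline_config(fs = cfg$fs))
  n <- nrow(res$scored)
  interior <- 2:(n - 1)
  expect_true(all(res$scored$compliant[interior]))
  v <- res$validation
  expect_true(all(v$valid[v$start %in% res$scored$start[interior]]))
})

test_that("validation results are independent of beat order", {
  cfg <- synth_config(n_beats = 10, artifact_fraction = 0, noise_sd = 0.03,
                      seed = 4)
  rec <- make_paired_dataset(cfg)
  pc <- pipeline_config(fs = cfg$fs)
  ppg_f <- ppg_bandpass(rec$ppg); ecg_f <- ecg_bandpass(rec$ecg)
  on <- detect_onsets(ppg_f)
  beats <- segment_beats(ppg_f, on)
  segs <- segment_ecg_by_onsets(ecg_f, on)
  ref <- ecg_reference()
  idx <- seq_along(beats)
  res_fwd <- lapply(idx, function(i) validate_ecg_beat(segs[[i]], beats[[i]], ref))
  perm <- rev(idx)
  res_rev <- lapply(perm, function(i) validate_ecg_beat(segs[[i]], beats[[i]], ref))
  for (j in idx)
    expect_identical(res_fwd[[perm[j]]], res_rev[[j]])
})

test_that("a PPG-only record skips the ECG stage", {
  cfg <- synth_config(n_beats = 8, artifact_fraction = 0, noise_sd = 0, seed = 2)
  rec <- make_paired_dataset(cfg, with_ecg = FALSE)
  res <- validate_record(rec$ppg, NULL, config = pipeline_config(fs = cfg$fs))
  expect_identical(nrow(res$validation), 0L)
  expect_gt(nrow(res$scored), 0L)
})
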