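#' Configuration for the synthetic paired-record generator
#'
#' Defines the simulated acquisition: sampling rate, beat count, heart-rate
#' model, global noise sources (white noise, 50 Hz powerline, baseline
#' wander) and the per-beat artifact model (motion lobe, sensor dropout,
#' spike). All randomness is driven by the integer `seed`; identical
#' configurations produce bit-identical records.
#'
#' @param fs Sampling rate in Hz.
#' @param n_beats Number of beats to generate.
#' @param mean_hr Mean heart rate in beats/min.
#' @param hr_jitter Fractional standard deviation of inter-beat intervals.
#' @param amplitude_jitter Fractional standard deviation of beat amplitude.
#' @param noise_sd Gaussian noise, as a fraction of the pulse amplitude.
#' @param powerline_amp 50 Hz amplitude, as a fraction of pulse amplitude.
#' @param baseline_wander Two-element vector: amplitude fraction and
#'   frequency (Hz) of the slow drift.
#' @param artifact_fraction Fraction of beats corrupted.
#' @param artifact_kinds Subset of `c("motion", "dropout", "spike")`.
#' @param ptt_delay_ms Delay of the second-site PPG in milliseconds.
#' @param r_offset_s R-peak lead time before each PPG onset, in seconds
#'   (pulse-arrival delay).
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 1000, n_beats = 60, mean_hr = 60,
                         hr_jitter = 0.03, amplitude_jitter = 0.05,
                         noise_sd = 0.05, powerline_amp = 0.05,
                         baseline_wander = c(0.2, 0.25),
                         artifact_fraction = 0.1,
                         artifact_kinds = c("motion", "dropout", "spike"),
                         ptt_delay_ms = 50, r_offset_s = 0.2, seed = 1) {
  stopifnot(fs > 0, n_beats >= 1, mean_hr > 0,
            hr_jitter >= 0, hr_jitter <= 1,
            amplitude_jitter >= 0, amplitude_jitter <= 1,
            noise_sd >= 0, noise_sd <= 1, powerline_amp >= 0,
            artifact_fraction >= 0, artifact_fraction <= 1,
            length(baseline_wander) == 2,
            all(artifact_kinds %in% c("motion", "dropout", "spike")))
  if (fs <= 2 * 50) stop("'fs' must exceed twice the highest generated frequency (50 Hz)")
  structure(list(fs = fs, n_beats = n_beats, mean_hr = mean_hr,
                 hr_jitter = hr_jitter, amplitude_jitter = amplitude_jitter,
                 noise_sd = noise_sd, powerline_amp = powerline_amp,
                 baseline_wander = baseline_wander,
                 artifact_fraction = artifact_fraction,
                 artifact_kinds = artifact_kinds,
                 ptt_delay_ms = ptt_delay_ms, r_offset_s = r_offset_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a clean PPG pulse train
#'
#' Concatenates per-beat copies of the reference template, each time-warped
#' to an inter-beat interval drawn from the heart-rate model and scaled by
#' an amplitude-jitter factor. Because the template is a min-to-min slice
#' (both endpoints at its minimum), consecutive beats join continuously.
#' Ground-truth onsets are the beat start indices.
#'
#' @param config A [synth_config()].
#' @param template A `ppg_template` (defaults to the built-in one).
#' @return An object of class `labeled_record` with elements `ppg`,
#'   `beat_onsets` (1-based sample indices), `beat_labels` (all `"clean"`),
#'   and `config`.
#' @export
gen_ppg_train <- function(config, template = default_template()) {
  stopifnot(inherits(config, "synth_config"), inherits(template, "ppg_template"))
  set.seed(config$seed)
  fs <- config$fs
  ibi <- (60 / config$mean_hr) * (1 + stats::rnorm(config$n_beats, 0, config$hr_jitter))
  ibi <- pmax(ibi, 0.3)                       # physiological floor
  lens <- pmax(8L, as.integer(round(ibi * fs)))
  amps <- pmax(0.2, 1 + stats::rnorm(config$n_beats, 0, config$amplitude_jitter))
  pieces <- lapply(seq_len(config$n_beats), function(i)
    amps[i] * rescale_to(template$samples, lens[i]))
  onsets <- cumsum(c(1L, lens[-config$n_beats]))
  structure(list(ppg = sampled_signal(unlist(pieces), fs, label = "ppg"),
                 ecg = NULL, site2_ppg = NULL,
                 beat_onsets = onsets,
                 beat_labels = rep("clean", config$n_beats),
                 config = config),
            class = "labeled_record")
}

#' Generate the paired synthetic ECG channel
#'
#' Places one Gaussian-sum PQRST pulse per beat, with the R peak
#' `r_offset_s` seconds before the paired PPG onset (the pulse-arrival
#' delay between the heart's electrical activation and the peripheral
#' pressure wave).
#'
#' @param config A [synth_config()].
#' @param onsets PPG onset indices (1-based).
#' @param n_total Record length in samples.
#' @param components PQRST Gaussian table, see [pqrst_components()].
#' @return An ECG [sampled_signal()].
#' @export
gen_ecg_train <- function(config, onsets, n_total,
                          components = pqrst_components()) {
  fs <- config$fs
  ecg <- numeric(n_total)
  t <- (seq_len(n_total) - 1) / fs
  for (on in onsets) {
    t_r <- (on - 1) / fs - config$r_offset_s
    w <- which(t >= t_r - 0.5 & t <= t_r + 0.6)
    if (length(w)) ecg[w] <- ecg[w] + gaussian_pqrst(t[w] - t_r, components)
  }
  sampled_signal(ecg, fs, label = "ecg")
}

#' Inject global noise and per-beat artifacts
#'
#' Adds Gaussian noise, a 50 Hz powerline component and slow baseline
#' wander to every channel, then corrupts a seeded random subset of beats
#' (fraction `artifact_fraction`) with one of: a smoothly windowed
#' low-frequency motion lobe spanning the beat (amplitude 0.7--1.4 times
#' the pulse, 2--5 cycles), a sensor dropout (the beat flatlines at its
#' onset level, losing all waveform information), or a spike (1--2 times
#' the pulse, 40--100 ms base). Motion and spike magnitudes are chosen so
#' the corruption carries in-band energy comparable to the pulse itself
#' (disturbances below the monitored band's resolution are removed by the
#' pre-filter and do not corrupt beat morphology) while the residue that
#' the acquisition chain smears into adjacent beats stays within their
#' noise floor, keeping the per-beat labels physically meaningful. A
#' flatlined beat, by
#' contrast, is information-free rather than distorted - after filtering
#' and per-beat renormalisation its residue can mimic a pulse, and
#' rejecting it is the task of the ECG AND gate (the missing R wave fails
#' the content check). Corruptions are applied to the PPG and ECG channels
#' alike; beat labels are updated. The artifact draw uses its own stream
#' seeded with `seed + 1`, so the corrupted set can be reproduced
#' independently of the waveform noise.
#'
#' @param record A `labeled_record`.
#' @param config The [synth_config()] used to build it.
#' @return The corrupted `labeled_record` with `beat_labels` updated and
#'   the chosen artifact kinds in `artifact_kind_per_beat`.
#' @export
inject_corruptions <- function(record, config) {
  stopifnot(inherits(record, "labeled_record"))
  fs <- config$fs
  n <- length(record$ppg$samples)
  t <- (seq_len(n) - 1) / fs

  set.seed(config$seed + 1L)
  nb <- length(record$beat_onsets)
  k <- round(config$artifact_fraction * nb)
  corrupted <- if (k > 0) sort(sample.int(nb, k)) else integer(0)
  kinds <- rep(NA_character_, nb)
  if (k > 0)
    kinds[corrupted] <- sample(config$artifact_kinds, k, replace = TRUE)

  bounds <- c(record$beat_onsets, n + 1L)
  ppg <- record$ppg$samples
  ecg <- if (!is.null(record$ecg)) record$ecg$samples else NULL
  for (i in corrupted) {
    idx <- bounds[i]:(bounds[i + 1] - 1L)
    m <- length(idx)
    kind <- kinds[i]
    if (kind == "motion") {
      cycles <- stats::runif(1, 2, 5)
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.7, 1.4)
      u <- seq(0, 1, length.out = m)
      # squared-Hann envelope: motion ramps in and out smoothly, so the
      # artifact stays confined to the labelled beat
      lobe <- amp * sin(2 * pi * cycles * u + phase) *
        (0.5 * (1 - cos(2 * pi * u)))^2
      ppg[idx] <- ppg[idx] + lobe
      if (!is.null(ecg)) ecg[idx] <- ecg[idx] + lobe
    } else if (kind == "dropout") {
      ppg[idx] <- ppg[idx[1]]                  # flatline at the onset level
      if (!is.null(ecg)) ecg[idx] <- ecg[idx[1]]
    } else {                                   # spike
      # placed in the beat's interior so the per-beat label stays valid
      # under the acquisition chain's temporal smearing
      pos <- idx[1] + round(m * stats::runif(1, 0.2, 0.8))
      hw <- max(2L, round(stats::runif(1, 0.02, 0.05) * fs))
      amp <- stats::runif(1, 1, 2)
      w <- max(1L, pos - hw):min(n, pos + hw)
      tri <- amp * (1 - abs(w - pos) / hw)
      ppg[w] <- ppg[w] + tri
      if (!is.null(ecg)) ecg[w] <- ecg[w] + tri
    }
  }

  # interference (mains pickup, respiration-like wander) is common-mode
  # across channels; only the sensor noise is independent
  bw_phase <- stats::runif(1, 0, 2 * pi)
  interference <- config$powerline_amp * sin(2 * pi * 50 * t) +
    config$baseline_wander[1] *
    sin(2 * pi * config$baseline_wander[2] * t + bw_phase)
  add_global <- function(x, scale) {
    x + scale * (config$noise_sd * stats::rnorm(length(x)) + interference)
  }
  record$ppg <- sampled_signal(add_global(ppg, 1), fs, label = "ppg")
  if (!is.null(ecg)) record$ecg <- sampled_signal(add_global(ecg, 1), fs, label = "ecg")
  if (!is.null(record$site2_ppg))
    record$site2_ppg <- sampled_signal(add_global(record$site2_ppg$samples, 1),
                                       fs, label = "ppg_site2")
  record$beat_labels[corrupted] <- "corrupted"
  record$artifact_kind_per_beat <- kinds
  record
}

#' Generate a complete paired PPG + ECG dataset
#'
#' Composes [gen_ppg_train()], [gen_ecg_train()], an optional delayed
#' second-site PPG, and [inject_corruptions()], returning a fully
#' labelled record ready for the screening pipeline.
#'
#' @param config A [synth_config()].
#' @param template A `ppg_template`.
#' @param with_ecg Generate the paired ECG channel.
#' @param with_site2 Generate the delayed second-site PPG channel.
#' @return A `labeled_record` with `ppg`, `ecg`, `site2_ppg`,
#'   `beat_onsets`, `site2_onsets`, `beat_labels`.
#' @export
make_paired_dataset <- function(config = synth_config(),
                                template = default_template(),
                                with_ecg = TRUE, with_site2 = FALSE) {
  rec <- gen_ppg_train(config, template)
  n <- length(rec$ppg$samples)
  if (with_ecg)
    rec$ecg <- gen_ecg_train(config, rec$beat_onsets, n)
  if (with_site2) {
    d <- as.integer(round(config$ptt_delay_ms / 1000 * config$fs))
    x <- rec$ppg$samples
    site2 <- c(rep(x[1], d), x[seq_len(n - d)])
    rec$site2_ppg <- sampled_signal(site2, config$fs, label = "ppg_site2")
    rec$site2_onsets <- rec$beat_onsets + d
  }
  inject_corruptions(rec, config)
}

#' @export
print.labeled_record <- function(x, ...) {
  cat(sprintf("<labeled_record> %d beats (%d corrupted), %d samples @ %g Hz%s%s\n",
              length(x$beat_onsets), sum(x$beat_labels == "corrupted"),
              length(x$ppg$samples), x$ppg$fs,
              if (!is.null(x$ecg)) ", +ECG" else "",
              if (!is.null(x$site2_ppg)) ", +site2" else ""))
  invisible(x)
}

#' Score pipeline decisions against ground-truth beat labels
#'
#' Matches detected beats to the generator's ground-truth beats by onset
#' proximity (within half the median true inter-beat interval) and
#' computes confusion statistics, treating *rejection of a corrupted beat*
#' as a true positive. Boundary beats (first and last) are excluded: the
#' segmenter discards partial head/tail data by construction.
#'
#' @param record A `labeled_record` with ground truth.
#' @param result Output of [validate_record()] or [run_pipeline()].
#' @param stage `"final"` (ECG AND gate where ECG is present) or `"ppg"`
#'   (PPG compliance only).
#' @return List with `sensitivity`, `specificity`, `n_clean`,
#'   `n_corrupted` and the per-beat decision table.
#' @export
evaluate_screening <- function(record, result, stage = c("final", "ppg")) {
  stage <- match.arg(stage)
  stopifnot(inherits(record, "labeled_record"))
  scored <- if (!is.null(result$scored)) result$scored else result$report$scored
  validation <- if (!is.null(result$validation)) result$validation else NULL

  truth_on <- record$beat_onsets
  labels <- record$beat_labels
  interior <- setdiff(seq_along(truth_on), c(1L, length(truth_on)))
  tol <- stats::median(diff(truth_on)) / 2

  accepted_starts <- scored$start[scored$compliant]
  if (stage == "final" && !is.null(validation) && nrow(validation) > 0) {
    ok <- validation$start[validation$valid]
    accepted_starts <- intersect(accepted_starts, ok)
  }

  decide <- vapply(interior, function(i) {
    if (!length(accepted_starts)) return(FALSE)
    min(abs(accepted_starts - truth_on[i])) <= tol
  }, TRUE)

  lab <- labels[interior]
  n_cor <- sum(lab == "corrupted"); n_cln <- sum(lab == "clean")
  sens <- if (n_cor) sum(!decide[lab == "corrupted"]) / n_cor else NA_real_
  spec <- if (n_cln) sum(decide[lab == "clean"]) / n_cln else NA_real_
  list(sensitivity = sens, specificity = spec,
       n_clean = n_cln, n_corrupted = n_cor,
       table = data.frame(beat = interior, onset = truth_on[interior],
                          label = lab, accepted = decide))
}
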