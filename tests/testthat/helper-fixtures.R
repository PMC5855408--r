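# Shared fixtures. Template and filter designs are deterministic and
# cached inside the package for the whole test session.

fixture_template <- function(n_samples = 512) default_template(n_samples)

fixture_fs <- 1000

# clean PPG pulse train built directly from the template (no generator
# randomness): `n` beats of `len` samples each
fixture_train <- function(n = 5, len = 1000, template = fixture_template()) {
  rep_beat <- rescale_to(template$samples, len)
  sampled_signal(rep(rep_beat, n), fixture_fs, label = "ppg")
}

# brute-force cross-covariance oracle: literal double loop over the
# printed sum, written independently of sample_xcov
naive_xcov <- function(p1, p2, h) {
  ns <- length(p1)
  m1 <- sum(p1) / ns
  m2 <- sum(p2) / ns
  acc <- 0
  for (k in seq_len(ns - h)) acc <- acc + (p1[k] - m1) * (p2[k + h] - m2)
  acc / ns
}

naive_rho <- function(p1, p2, h, mode = "pearson") {
  g <- naive_xcov(p1, p2, h)
  g11 <- naive_xcov(p1, p1, 0)
  g22 <- naive_xcov(p2, p2, 0)
  if (mode == "pearson") g / sqrt(g11 * g22) else g / (g11 * g22)
}

# exhaustive local-extrema scan (oracle for fiducial detection)
naive_local_minima <- function(x) {
  which(diff(sign(diff(x))) > 0) + 1L
}
naive_local_maxima <- function(x) {
  which(diff(sign(diff(x))) < 0) + 1L
}
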