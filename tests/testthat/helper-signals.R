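# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

fixture_fs <- 200

# Clean two-channel PPG + artifact + per-channel mixtures at one SNR.
make_mixture_fixture <- function(seed = 42, snr_db = 0, hr = 1.25,
                                 jitter = 0.02, model = "composite") {
  ppg <- generate_clean_ppg(ppg_model_params(
    heart_rate_hz = hr, hr_jitter_frac = jitter, seed = seed))
  ma <- generate_artifact(artifact_model_params(
    model = model, seed = seed + 1000L))
  mx <- mix_two_channel(ppg, ma, snr_db)
  list(ppg = ppg, ma = ma, mix = mx,
       corrupted = two_channel_ppg(mx$red$x, mx$ir$x),
       true_period = fixture_fs / hr)
}

# Orthogonal 2x2 mixing of one clean PPG source and one artifact source
# (the well-posed two-source ICA problem).
make_orthogonal_mixture <- function(seed = 1, angle = pi / 7,
                                    model = "band_noise") {
  ppg <- generate_clean_ppg(ppg_model_params(
    hr_jitter_frac = 0.02, sensor_noise_rms = 0, seed = seed))
  s <- ppg$ir$samples / sd(ppg$ir$samples)
  ma <- generate_artifact(artifact_model_params(
    model = model, seed = seed + 500L))
  a <- ma$samples / sd(ma$samples)
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2)
  X <- R %*% rbind(s, a)
  list(s = s, a = a, X = X, mixing = R,
       true_period = fixture_fs / attr(ppg, "params")$heart_rate_hz)
}

# Exhaustive direction search in the whitened 2-space: the independent
# oracle for the one-unit extraction (fine angular grid).
grid_oracle <- function(Z, rstd, contrast = "logcosh",
                        step_deg = 0.5) {
  cf <- ppgclean:::contrast_funs(contrast)
  th <- seq(0, pi, by = step_deg * pi / 180)
  stats <- vapply(th, function(a) {
    w <- c(cos(a), sin(a))
    y <- drop(crossprod(Z, w))
    c(J = (mean(cf$G(y)) - cf$EGv)^2,
      eps = 2 * (1 - abs(stats::cor(y, rstd))))
  }, numeric(2))
  list(theta = th, J = stats["J", ], eps = stats["eps", ])
}

rel_err <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Random invertible 2x2 mixing with bounded conditioning.
with_seed_matrix <- function(seed) {
  set.seed(seed + 9000)
  repeat {
    A <- matrix(rnorm(4), 2)
    sv <- svd(A)$d
    if (sv[1] / sv[2] < 10) return(A)
  }
}
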