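test_that("clean-PPG generator honours duration, amplitude ratio and seed", {
  p <- ppg_model_params(duration_s = 20, fs = 200, seed = 7,
                        red_ir_amplitude_ratio = 0.62)
  ppg <- generate_clean_ppg(p)
  expect_length(ppg$ir$samples, 4000L)
  expect_length(ppg$red$samples, 4000L)
  expect_equal(ts_rms(ppg$red) / ts_rms(ppg$ir), 0.62, tolerance = 1e-12)
  expect_equal(mean(ppg$ir$samples), 0, tolerance = 1e-12)
  expect_equal(mean(ppg$red$samples), 0, tolerance = 1e-12)

  again <- generate_clean_ppg(p)
  expect_identical(ppg$ir$samples, again$ir$samples)
  expect_identical(ppg$red$samples, again$red$samples)
})

test_that("generated waveform is quasi-periodic at the requested rate", {
  # oracle: argmax of the full biased autocorrelation over the
  # physiological lag range
  ppg <- generate_clean_ppg(ppg_model_params(heart_rate_hz = 1.25,
                                             hr_jitter_frac = 0, seed = 1))
  xv <- ppg$ir$samples
  r <- drop(acf(xv, lag.max = 400, plot = FALSE, demean = TRUE)$acf)
  lag <- 50:400
  best <- lag[which.max(r[lag + 1])]
  expect_lte(abs(best - 160), 1)

  est <- estimate_period(ppg$ir)
  expect_lte(abs(est$period_samples - 160), 1)
})

test_that("artifact models are reproducible, zero mean and band-faithful", {
  p <- artifact_model_params(model = "band_noise", band_hz = c(0.1, 4),
                             duration_s = 20, fs = 200, seed = 5)
  a <- generate_artifact(p)
  expect_identical(a$samples, generate_artifact(p)$samples)
  expect_equal(mean(a$samples), 0, tolerance = 1e-10)

  # oracle: direct periodogram integration
  pg <- Mod(fft(a$samples))^2
  f <- (seq_along(pg) - 1) * 200 / length(pg)
  f <- pmin(f, 200 - f)
  in_band <- sum(pg[f >= 0.1 & f <= 4]) / sum(pg)
  expect_gte(in_band, 0.5)

  for (m in c("random_walk", "transient_bumps", "composite")) {
    am <- generate_artifact(artifact_model_params(model = m, seed = 2))
    expect_equal(mean(am$samples), 0, tolerance = 1e-10)
    # spectral energy must overlap the PPG band
    pg <- Mod(fft(am$samples))^2
    expect_gt(sum(pg[f >= 0.5 & f <= 4]) / sum(pg), 0.05)
  }

  zero <- generate_artifact(artifact_model_params(
    model = "transient_bumps", bump_rate_hz = 0, seed = 1))
  expect_true(all(zero$samples == 0))

  expect_error(artifact_model_params(band_hz = c(4, 0.1)), "interval")
  expect_error(artifact_model_params(band_hz = c(0.1, 150), fs = 200),
               "fs/2")
})

test_that("mix_at_snr uses the closed-form scale and round-trips the SNR", {
  n <- 1000
  s <- ppg_ts(sqrt(2) * sin(2 * pi * (1:n) / 50), 100)   # RMS 1
  m <- ppg_ts(rep(c(1, -1), n / 2), 100)                 # RMS 1
  expect_equal(mix_at_snr(s, m, 0)$lam, 1, tolerance = 1e-12)

  # RMS(s) = 2, RMS(ma) = 1, snr 20 dB -> lam = 0.2
  s2 <- ppg_ts(2 * s$samples / ts_rms(s), 100)
  mx <- mix_at_snr(s2, m, 20)
  expect_equal(mx$lam, 0.2, tolerance = 1e-12)
  expect_equal(20 * log10(ts_rms(s2) / (mx$lam * ts_rms(m))), 20,
               tolerance = 1e-9)
  expect_equal(mx$x$samples, s2$samples + mx$lam * m$samples)

  expect_error(mix_at_snr(ppg_ts(rep(0, 10), 1), ppg_ts(rnorm(10), 1), 0),
               "degenerate")
})

test_that("Eq.-7 round trip holds across random draws and SNRs", {
  set.seed(31)
  for (i in 1:20) {
    fix <- make_mixture_fixture(seed = i)
    snr <- runif(1, -30, 30)
    mx <- mix_at_snr(fix$ppg$ir, fix$ma, snr)
    achieved <- 20 * log10(ts_rms(fix$ppg$ir) / (mx$lam * ts_rms(fix$ma)))
    expect_lte(abs(achieved - snr), 1e-9)
  }
})

test_that("two-channel mixing shares one artifact waveform and anchors IR", {
  fix <- make_mixture_fixture(seed = 9, snr_db = 0)
  mx <- fix$mix
  expect_equal(mx$ir$snr_db, 0, tolerance = 1e-9)
  # same waveform, channel-specific scale
  red_ma <- mx$red$x$samples - fix$ppg$red$samples
  ir_ma <- mx$ir$x$samples - fix$ppg$ir$samples
  expect_equal(red_ma / mx$red$lam, ir_ma / mx$ir$lam, tolerance = 1e-9)
  # default wavelength-independent coupling
  expect_equal(mx$red$lam, mx$ir$lam, tolerance = 1e-12)
})

test_that("rrmse reports identity, scale and gross errors as specified", {
  s <- ppg_ts(rnorm(500) + sin(1:500 / 10), 100)
  expect_equal(rrmse(s, s), 0)
  expect_equal(rrmse(s, ppg_ts(rep(0, 500), 100)), 100)
  expect_equal(rrmse(s, ppg_ts(2 * s$samples, 100)), 100)
  for (a in c(-1, 0.25, 1.7))
    expect_equal(rrmse(s, a * s$samples), 100 * abs(1 - a),
                 tolerance = 1e-9)
  expect_error(rrmse(s, rnorm(10)), "equal length")
  expect_error(rrmse(rep(0, 5), rnorm(5)), "degenerate")
})
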