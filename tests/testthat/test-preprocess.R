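test_that("FIR design meets the stopband and passband specification", {
  spec <- design_lowpass(200)
  expect_lte(20 * log10(Mod(filter_response(spec, 8))), -20)
  expect_equal(Mod(filter_response(spec, 0)), 1, tolerance = 1e-3)
  # passband ripple <= 1 dB over the PPG band
  gains_db <- 20 * log10(Mod(filter_response(spec, seq(0.1, 4, 0.1))))
  expect_lte(max(abs(gains_db)), 1)
  expect_error(design_lowpass(15), "twice the stopband")
})

test_that("stopband attenuation holds across sampling rates", {
  for (fs in c(100, 200, 500, 1000)) {
    spec <- design_lowpass(fs)
    expect_lte(20 * log10(Mod(filter_response(spec, 8))), -20)
  }
})

test_that("zero-phase low-pass is transparent to an in-band tone", {
  # oracle: direct frequency-response evaluation at 1 Hz
  fs <- 200
  t <- (0:3999) / fs
  x <- ppg_ts(sin(2 * pi * 1 * t), fs)
  spec <- design_lowpass(fs)
  y <- apply_lowpass(x, spec)
  amp_ratio <- ts_rms(y) / ts_rms(x)
  expect_lte(abs(20 * log10(amp_ratio)), 1)
  expect_equal(amp_ratio, Mod(filter_response(spec, 1))^2,
               tolerance = 1e-3)
})

test_that("DC-removal recursion matches its difference equation exactly", {
  # oracle: symbolic unrolling of y(n) = x(n) - x(n-1) + 0.992 y(n-1)
  step <- rep(1, 50)
  y <- remove_dc(step)
  expect_equal(y[1], 1)
  expect_equal(y[-1], 0.992^(1:49), tolerance = 1e-12)

  # DC gain is exactly zero: numerator coefficients sum to 0; the
  # transient decays as 0.992^n (time constant 125 samples)
  const <- remove_dc(rep(7, 4000))
  expect_lt(max(abs(const[3000:4000])), 1e-6 * 7)

  # arbitrary input vs direct recursion
  set.seed(4)
  x <- rnorm(300)
  ref <- numeric(300)
  ref[1] <- x[1]
  for (n in 2:300) ref[n] <- x[n] - x[n - 1] + 0.992 * ref[n - 1]
  expect_equal(remove_dc(x), ref, tolerance = 1e-12)
})

test_that("DC removal is linear and time-invariant", {
  set.seed(11)
  for (i in 1:5) {
    x1 <- rnorm(400); x2 <- rnorm(400)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(remove_dc(a * x1 + b * x2),
                 a * remove_dc(x1) + b * remove_dc(x2),
                 tolerance = 1e-9)
  }
})

test_that("period estimation recovers known fundamentals", {
  # pure 2 Hz sinusoid at 200 Hz -> 100 samples
  t <- (0:3999) / 200
  est <- estimate_period(ppg_ts(sin(2 * pi * 2 * t), 200))
  expect_lte(abs(est$period_samples - 100), 0.5)

  # clean PPG at 1.25 Hz -> 160 samples
  ppg <- generate_clean_ppg(ppg_model_params(hr_jitter_frac = 0, seed = 2))
  est <- estimate_period(ppg$ir)
  expect_lte(abs(est$period_samples - 160), 1)

  expect_error(estimate_period(ppg_ts(rep(0, 4000), 200)), "degenerate")
  expect_error(estimate_period(ppg_ts(rnorm(400), 200)), "too short")
})

test_that("period survives a 0 dB mixture within 5%", {
  fix <- make_mixture_fixture(seed = 42, snr_db = 0)
  pre <- preprocess_channel(fix$corrupted$ir, pipeline_config())
  est <- estimate_period(pre)
  expect_lte(abs(est$period_samples - fix$true_period) / fix$true_period,
             0.05)
})

test_that("reference pulse train has the stated shape and moments", {
  ref <- make_reference(160, 4000, duty = 0.2)
  expect_length(ref$samples, 4000L)
  expect_equal(mean(ref$samples), 0, tolerance = 1e-9)
  expect_equal(var(ref$samples), 1, tolerance = 1e-9)
  # exactly floor(4000/160) = 25 pulse onsets (rising edges)
  high <- ref$samples > 0
  expect_identical(sum(diff(high) == 1) + as.integer(high[1]), 25L)

  expect_error(make_reference(160, 4000, duty = 1.2), "duty")
  expect_error(make_reference(1, 4000), "period_samples")
})

test_that("estimate_period and make_reference close the loop", {
  for (p in seq(50, 400, by = 50)) {
    ref <- make_reference(p, 8000, duty = 0.2, fs = 200)
    est <- estimate_period(ref)
    expect_lte(abs(est$period_samples - p), 1)
  }
})

test_that("aligned reference locks onto the waveform phase", {
  ppg <- generate_clean_ppg(ppg_model_params(hr_jitter_frac = 0, seed = 6))
  ref0 <- make_reference(160, 4000, fs = 200)
  refA <- make_aligned_reference(ppg$ir, 160)
  expect_gte(cor(refA$samples, ppg$ir$samples),
             cor(ref0$samples, ppg$ir$samples))
  expect_gt(cor(refA$samples, ppg$ir$samples), 0.4)
})
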