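test_that("whitening yields identity covariance and flags degeneracy", {
  set.seed(8)
  X <- matrix(rnorm(2 * 3000), 2)
  wh <- whiten(X)
  expect_equal(cov(t(wh$Z)), diag(2), tolerance = 1e-8)
  expect_equal(wh$mean_vector, rowMeans(X), tolerance = 1e-12)

  # random correlated data: oracle = eigendecomposition of covariance
  A <- matrix(c(2, 0.5, 0.3, 1), 2)
  Xc <- A %*% matrix(rnorm(2 * 3000), 2)
  expect_equal(cov(t(whiten(Xc)$Z)), diag(2), tolerance = 1e-8)

  base <- rnorm(1000)
  expect_error(whiten(rbind(base, 2 * base)), "degenerate")
})

test_that("closeness is a sign-folded correlation distance", {
  set.seed(2)
  r <- rnorm(5000)
  expect_equal(closeness(r, r), 0)
  expect_equal(closeness(-r, r), 0)
  y <- rnorm(1e5); r2 <- rnorm(1e5)
  expect_lte(abs(closeness(y, r2) - 2), 0.05)
  expect_error(closeness(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("extraction recovers the planted PPG source from an orthogonal mixing", {
  fix <- make_orthogonal_mixture(seed = 3)
  ref <- make_aligned_reference(ppg_ts(fix$X[2, ], fixture_fs),
                                fix$true_period)
  res <- extract_component(fix$X, ref)
  expect_gte(abs(cor(res$y$samples, fix$s)), 0.95)
  expect_equal(var(res$y$samples), 1, tolerance = 1e-6)
  expect_true(res$converged)

  # agreement with the exhaustive grid oracle: same feasible optimum of J
  wh <- whiten(fix$X)
  rstd <- (ref$samples - mean(ref$samples)) / sd(ref$samples)
  g <- grid_oracle(wh$Z, rstd)
  feasible <- g$eps <= res$xi + 1e-6
  expect_true(any(feasible))
  J_best <- max(g$J[feasible])
  expect_lte(abs(res$negentropy - J_best) / J_best, 0.01)
})

test_that("the reference, not source order, selects the output", {
  # swap experiment: reference built from the artifact's period makes
  # the extraction return the artifact source
  ppg <- generate_clean_ppg(ppg_model_params(hr_jitter_frac = 0.02,
                                             sensor_noise_rms = 0,
                                             seed = 12))
  s <- ppg$ir$samples / sd(ppg$ir$samples)
  t <- (seq_along(s) - 1) / fixture_fs
  tone <- sin(2 * pi * 0.3 * t)            # slow artifact, period 666.7
  a <- tone / sd(tone)
  R <- matrix(c(cos(0.5), -sin(0.5), sin(0.5), cos(0.5)), 2)
  X <- R %*% rbind(s, a)

  ref_ppg <- make_aligned_reference(ppg_ts(X[2, ], fixture_fs),
                                    fixture_fs / 1.25)
  ref_art <- make_aligned_reference(ppg_ts(X[2, ], fixture_fs),
                                    fixture_fs / 0.3)
  y_ppg <- extract_component(X, ref_ppg)$y$samples
  y_art <- extract_component(X, ref_art)$y$samples
  expect_gte(abs(cor(y_ppg, s)), 0.95)
  expect_gte(abs(cor(y_art, a)), 0.95)
})

test_that("random invertible mixings are resolved in >= 90% of seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (i in seq_len(n_seeds)) {
    ppg <- generate_clean_ppg(ppg_model_params(
      hr_jitter_frac = 0.02, sensor_noise_rms = 0, seed = i))
    s <- ppg$ir$samples / sd(ppg$ir$samples)
    ma <- generate_artifact(artifact_model_params(model = "band_noise",
                                                  seed = i + 700L))
    a <- ma$samples / sd(ma$samples)
    A <- with_seed_matrix(i)
    X <- A %*% rbind(s, a)
    ref <- make_aligned_reference(ppg_ts(X[2, ], fixture_fs),
                                  fixture_fs / 1.25)
    y <- extract_component(X, ref)$y$samples
    if (abs(cor(y, s)) >= 0.95) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("per-channel gain does not change the extracted component", {
  fix <- make_orthogonal_mixture(seed = 5)
  ref <- make_aligned_reference(ppg_ts(fix$X[2, ], fixture_fs),
                                fix$true_period)
  y1 <- extract_component(fix$X, ref)$y$samples
  X2 <- fix$X * c(5, 1)                   # rescale channel 1
  y2 <- extract_component(X2, ref)$y$samples
  expect_gte(abs(cor(y1, y2)), 0.999)
})

test_that("degenerate references and length mismatches are rejected", {
  fix <- make_orthogonal_mixture(seed = 2)
  expect_error(extract_component(fix$X, rep(1, ncol(fix$X))),
               "degenerate")
  expect_error(extract_component(fix$X, rnorm(10)), "same length")
})
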