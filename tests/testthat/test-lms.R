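test_that("LMS converges to the Wiener gain on a proportional target", {
  set.seed(1)
  u <- rnorm(1e4)
  res <- lms(u, 0.5 * u, lms_params(order = 1, mu = 0.5))
  expect_lte(abs(res$w_final - 0.5), 1e-3)      # oracle: E[ud]/E[u^2]
  res_neg <- lms(u, -0.5 * u, lms_params(order = 1, mu = 0.5))
  expect_lte(abs(res_neg$w_final + 0.5), 1e-3)
  expect_false(res$diverged)
})

test_that("a zero step size freezes the filter", {
  set.seed(2)
  u <- rnorm(500)
  d <- rnorm(500)
  w0 <- c(0.3, -0.1, 0.2)
  res <- lms(u, d, lms_params(order = 3, mu = 0, w_init = w0))
  expect_equal(res$w_final, w0)
  ref <- as.numeric(stats::filter(u, w0, sides = 1))
  ref[is.na(ref)] <- cumsum(u * 0)[seq_len(2)] # first two: partial taps
  ref[1] <- w0[1] * u[1]
  ref[2] <- w0[1] * u[2] + w0[2] * u[1]
  expect_equal(res$y, ref)
  expect_error(lms_params(mu = -0.1), "non-negative")
})

test_that("d = y + e holds exactly for adaptive and frozen fits", {
  set.seed(3)
  u <- rnorm(3000)
  d <- rnorm(3000)
  for (fit in list(lms(u, d), lms_fit(u, d))) {
    expect_lte(max(abs(d - (fit$y + fit$e))), 1e-10 * sd(d))
  }
})

test_that("converged taps match the closed-form least-squares solution", {
  # oracle: LS fit of d on the delay-line matrix of u
  set.seed(9)
  n <- 2e4
  u <- as.numeric(stats::filter(rnorm(n), c(1, 0.4), sides = 1))
  u[is.na(u)] <- 0
  h <- c(0.7, -0.3, 0.15, 0.05)
  d <- as.numeric(stats::filter(u, h, sides = 1))
  d[is.na(d)] <- 0
  d <- d + 0.05 * rnorm(n)
  L <- 6
  res <- lms_fit(u, d, lms_params(order = L, mu = 0.2, passes = 4))
  U <- sapply(seq_len(L), function(k) c(rep(0, k - 1), u[1:(n - k + 1)]))
  w_ls <- qr.solve(U, d)
  expect_lte(sqrt(sum((res$w_final - w_ls)^2)) / sqrt(sum(w_ls^2)), 0.05)
})

test_that("normalized stepping never diverges on generator signals", {
  for (i in 1:50) {
    fix <- make_mixture_fixture(seed = i, snr_db = (i %% 21) - 10)
    res <- lms(fix$ma$samples, fix$corrupted$ir$samples,
               lms_params(order = 8, mu = 1))
    expect_false(res$diverged)
  }
})

test_that("amplitude recovery restores channel scale from a unit component", {
  # oracle: least-squares projection of d onto the delay span of u
  set.seed(21)
  ppg <- generate_clean_ppg(ppg_model_params(seed = 33))
  clean <- ppg$ir$samples
  n <- length(clean)
  a <- 3.7
  u <- clean / sd(clean)
  L <- 16
  # artifact orthogonal to the component's delay span, per the stated
  # premise (artifact and clean uncorrelated)
  ma <- generate_artifact(artifact_model_params(model = "band_noise",
                                                seed = 44))$samples
  U <- sapply(seq_len(L), function(k) c(rep(0, k - 1), u[1:(n - k + 1)]))
  ma <- ma - as.numeric(U %*% qr.solve(U, ma))
  d <- ppg_ts(a * clean + sd(a * clean) * ma / sd(ma), 200)
  comp <- ppg_ts(u, 200)

  pars <- lms_params(order = L)
  rec <- recover_amplitude(d, comp, pars)
  target <- a * clean
  expect_lte(rel_err(rec$recovered_ppg$samples, target), 0.1)

  # sign flip of the component is absorbed by the taps
  rec2 <- recover_amplitude(d, ppg_ts(-comp$samples, 200), pars)
  expect_lte(max(abs(rec2$recovered_ppg$samples -
                       rec$recovered_ppg$samples)),
             1e-6 * sd(target))

  # exact additive split
  expect_lte(max(abs(d$samples - (rec$recovered_ppg$samples +
                                    rec$ma_estimate$samples))),
             1e-10 * sd(d$samples))
})
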