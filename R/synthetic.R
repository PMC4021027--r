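#' Parameters of the synthetic clean-PPG generator
#'
#' The clean PPG model is a quasi-periodic waveform: a sum of
#' `n_harmonics` sinusoidal harmonics of the heart rate with geometrically
#' decaying amplitudes, plus a delayed, attenuated copy of that harmonic
#' stack standing in for the dicrotic notch. Cycle-to-cycle period jitter
#' is applied by warping the instantaneous phase, so the waveform is
#' quasi-periodic rather than strictly periodic. The red channel shares
#' the infrared channel's fundamental and phase track but has a
#' wavelength-dependent morphology (slower harmonic decay, weaker dicrotic
#' wave) and is rescaled so that `RMS(red)/RMS(ir)` equals
#' `red_ir_amplitude_ratio` exactly.
#'
#' @param heart_rate_hz fundamental frequency in Hz; must lie in the PPG
#'   band 0.5--4 Hz.
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz.
#' @param n_harmonics number of harmonics (>= 1).
#' @param harmonic_decay per-harmonic amplitude ratio in (0, 1) for the
#'   infrared channel.
#' @param dicrotic_delay_frac delay of the dicrotic surrogate as a fraction
#'   of the cycle, in (0, 1).
#' @param dicrotic_gain amplitude of the dicrotic surrogate relative to the
#'   primary wave.
#' @param hr_jitter_frac standard deviation of the cycle-to-cycle period
#'   jitter, as a fraction of the nominal period (>= 0).
#' @param red_ir_amplitude_ratio exact RMS ratio red/ir (> 0).
#' @param red_decay_shift additive shift of `harmonic_decay` for the red
#'   channel (wavelength-dependent morphology; red and IR pulse shapes
#'   are nearly, but not exactly, identical).
#' @param red_dicrotic_scale multiplier on `dicrotic_gain` for the red
#'   channel.
#' @param sensor_noise_rms RMS of independent white sensor noise added
#'   to each channel, relative to the channel's clean RMS (>= 0).
#' @param seed integer RNG seed; the generator is bit-reproducible.
#'
#' @return A validated parameter list of class `ppg_model_params`.
#' @export
ppg_model_params <- function(heart_rate_hz = 1.25,
                             duration_s = 20,
                             fs = 200,
                             n_harmonics = 8L,
                             harmonic_decay = 0.5,
                             dicrotic_delay_frac = 0.35,
                             dicrotic_gain = 0.4,
                             hr_jitter_frac = 0.02,
                             red_ir_amplitude_ratio = 0.5,
                             red_decay_shift = 0.04,
                             red_dicrotic_scale = 0.85,
                             sensor_noise_rms = 0.01,
                             seed = 1L) {
  if (heart_rate_hz < 0.5 || heart_rate_hz > 4)
    stop("`heart_rate_hz` must lie in the PPG band [0.5, 4] Hz", call. = FALSE)
  if (duration_s <= 0 || fs <= 0)
    stop("`duration_s` and `fs` must be positive", call. = FALSE)
  if (n_harmonics < 1)
    stop("`n_harmonics` must be >= 1", call. = FALSE)
  if (harmonic_decay <= 0 || harmonic_decay >= 1)
    stop("`harmonic_decay` must lie in (0, 1)", call. = FALSE)
  if (dicrotic_delay_frac <= 0 || dicrotic_delay_frac >= 1)
    stop("`dicrotic_delay_frac` must lie in (0, 1)", call. = FALSE)
  if (hr_jitter_frac < 0)
    stop("`hr_jitter_frac` must be >= 0", call. = FALSE)
  if (red_ir_amplitude_ratio <= 0)
    stop("`red_ir_amplitude_ratio` must be > 0", call. = FALSE)
  structure(list(heart_rate_hz = heart_rate_hz, duration_s = duration_s,
                 fs = fs, n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 dicrotic_delay_frac = dicrotic_delay_frac,
                 dicrotic_gain = dicrotic_gain,
                 hr_jitter_frac = hr_jitter_frac,
                 red_ir_amplitude_ratio = red_ir_amplitude_ratio,
                 red_decay_shift = red_decay_shift,
                 red_dicrotic_scale = red_dicrotic_scale,
                 sensor_noise_rms = sensor_noise_rms,
                 seed = as.integer(seed)),
            class = "ppg_model_params")
}

# Harmonic-stack waveform evaluated at cycle phase u (in cycles): primary
# wave plus delayed, attenuated copy (dicrotic surrogate).
harmonic_cycle <- function(u, n_harmonics, decay, dicrotic_gain, dicrotic_delay) {
  out <- numeric(length(u))
  for (k in seq_len(n_harmonics)) {
    a <- decay^(k - 1)
    out <- out + a * sin(2 * pi * k * u) +
      dicrotic_gain * a * sin(2 * pi * k * (u - dicrotic_delay))
  }
  out
}

#' Generate a synthetic clean two-channel PPG record
#'
#' @param params a [ppg_model_params()] list.
#'
#' @return A [two_channel_ppg()] with zero-mean channels whose RMS ratio
#'   red/ir equals `params$red_ir_amplitude_ratio` exactly. The mean cycle
#'   period in seconds is attached as attribute `"mean_period_s"`.
#' @export
#' @examples
#' ppg <- generate_clean_ppg(ppg_model_params(duration_s = 20, fs = 200))
#' length(ppg$ir$samples)  # 4000
generate_clean_ppg <- function(params) {
  stopifnot(inherits(params, "ppg_model_params"))
  p <- params
  n <- round(p$duration_s * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  nominal <- 1 / p$heart_rate_hz
  n_cycles <- ceiling(p$duration_s / nominal) + 2L

  phase <- with_seed(p$seed, {
    jit <- 1 + p$hr_jitter_frac * pmax(-3, pmin(3, rnorm(n_cycles)))
    periods <- nominal * jit
    bounds <- c(0, cumsum(periods))
    # piecewise-linear phase: k cycles completed at bounds[k + 1]
    idx <- findInterval(t, bounds, rightmost.closed = FALSE)
    (idx - 1) + (t - bounds[idx]) / periods[idx]
  })

  ir <- harmonic_cycle(phase, p$n_harmonics, p$harmonic_decay,
                       p$dicrotic_gain, p$dicrotic_delay_frac)
  red <- harmonic_cycle(phase, p$n_harmonics,
                        min(0.95, p$harmonic_decay + p$red_decay_shift),
                        p$dicrotic_gain * p$red_dicrotic_scale,
                        p$dicrotic_delay_frac)
  if (p$sensor_noise_rms > 0) {
    noise <- with_seed(p$seed + 1L, matrix(rnorm(2 * n), 2))
    ir <- ir + p$sensor_noise_rms * sqrt(mean(ir^2)) * noise[1, ]
    red <- red + p$sensor_noise_rms * sqrt(mean(red^2)) * noise[2, ]
  }
  ir <- ir - mean(ir)
  red <- red - mean(red)
  red <- red * (p$red_ir_amplitude_ratio * ts_rms(ir) / ts_rms(red))

  out <- two_channel_ppg(ppg_ts(red, p$fs), ppg_ts(ir, p$fs))
  attr(out, "mean_period_s") <- nominal
  attr(out, "params") <- p
  out
}

#' Parameters of the synthetic motion-artifact generator
#'
#' Four surrogate artifact models spanning the artifact morphologies seen
#' in motion-corrupted PPG: `band_noise` (Gaussian noise brick-wall
#' band-limited by spectral shaping), `random_walk` (integrated white
#' noise, detrended so only in-band drift remains), `transient_bumps`
#' (randomly timed smooth Gaussian-shaped excursions), and `composite`
#' (an RMS-weighted blend of the three). All models produce zero-mean,
#' unit-RMS signals (except the degenerate all-zero bump case) with
#' spectral energy overlapping the 0.5--4 Hz PPG band.
#'
#' @param model artifact model name.
#' @param band_hz for `band_noise` (and the band-noise part of
#'   `composite`): frequency interval in Hz to retain.
#' @param duration_s,fs record duration (s) and sampling rate (Hz).
#' @param walk_detrend_s window (s) of the moving average subtracted from
#'   the random walk to remove sub-band drift.
#' @param bump_rate_hz expected bump count per second (>= 0).
#' @param bump_width_s characteristic bump width in seconds.
#' @param weights RMS weights of the three parts in the composite model.
#' @param seed integer RNG seed.
#'
#' @return A validated list of class `artifact_model_params`.
#' @export
artifact_model_params <- function(model = c("composite", "band_noise",
                                            "random_walk", "transient_bumps"),
                                  band_hz = c(0.1, 4),
                                  duration_s = 20,
                                  fs = 200,
                                  walk_detrend_s = 4,
                                  bump_rate_hz = 0.3,
                                  bump_width_s = 0.35,
                                  weights = c(band_noise = 0.5,
                                              random_walk = 0.3,
                                              transient_bumps = 0.2),
                                  seed = 1L) {
  model <- match.arg(model)
  if (duration_s <= 0 || fs <= 0)
    stop("`duration_s` and `fs` must be positive", call. = FALSE)
  band_hz <- as.numeric(band_hz)
  if (length(band_hz) != 2L || !all(is.finite(band_hz)) ||
      band_hz[1] >= band_hz[2])
    stop("`band_hz` must be a non-empty interval c(lo, hi)", call. = FALSE)
  if (band_hz[1] < 0 || band_hz[2] > fs / 2)
    stop("`band_hz` must lie within [0, fs/2]", call. = FALSE)
  if (bump_rate_hz < 0)
    stop("`bump_rate_hz` must be >= 0", call. = FALSE)
  structure(list(model = model, band_hz = band_hz, duration_s = duration_s,
                 fs = fs, walk_detrend_s = walk_detrend_s,
                 bump_rate_hz = bump_rate_hz, bump_width_s = bump_width_s,
                 weights = weights, seed = as.integer(seed)),
            class = "artifact_model_params")
}

gen_band_noise <- function(n, fs, band_hz) {
  w <- rnorm(n)
  X <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)               # map negative-frequency bins
  keep <- f_fold >= band_hz[1] & f_fold <= band_hz[2]
  X[!keep] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  x - mean(x)
}

gen_random_walk <- function(n, fs, detrend_s) {
  x <- cumsum(rnorm(n))
  w <- max(3L, round(detrend_s * fs))
  x <- x - moving_average(x, w)           # drop sub-band drift
  x - mean(x)
}

gen_transient_bumps <- function(n, fs, rate_hz, width_s) {
  duration <- n / fs
  k <- rpois(1, rate_hz * duration)
  if (k == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  centers <- runif(k, 0, duration)
  amps <- rnorm(k)
  widths <- width_s * (0.5 + runif(k))
  x <- numeric(n)
  for (i in seq_len(k))
    x <- x + amps[i] * exp(-(t - centers[i])^2 / (2 * widths[i]^2))
  x - mean(x)
}

unit_rms <- function(x) {
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Generate a synthetic motion-artifact waveform
#'
#' @param params an [artifact_model_params()] list.
#' @return A zero-mean `ppg_ts`; unit RMS unless degenerate (zero bump
#'   rate under `model = "transient_bumps"` gives an all-zero signal).
#' @export
generate_artifact <- function(params) {
  stopifnot(inherits(params, "artifact_model_params"))
  p <- params
  n <- round(p$duration_s * p$fs)
  x <- with_seed(p$seed, {
    switch(p$model,
      band_noise = unit_rms(gen_band_noise(n, p$fs, p$band_hz)),
      random_walk = unit_rms(gen_random_walk(n, p$fs, p$walk_detrend_s)),
      transient_bumps = {
        b <- gen_transient_bumps(n, p$fs, p$bump_rate_hz, p$bump_width_s)
        if (all(b == 0)) b else unit_rms(b)
      },
      composite = {
        w <- p$weights / sum(p$weights)
        parts <- w["band_noise"] * unit_rms(gen_band_noise(n, p$fs, p$band_hz)) +
          w["random_walk"] * unit_rms(gen_random_walk(n, p$fs, p$walk_detrend_s)) +
          w["transient_bumps"] *
            unit_rms(gen_transient_bumps(n, p$fs, p$bump_rate_hz, p$bump_width_s))
        unit_rms(parts - mean(parts))
      })
  })
  ppg_ts(x, p$fs)
}

#' Mix a clean signal with an artifact at a target SNR
#'
#' Forms `x = s + lam * ma` with the scale `lam` chosen in closed form so
#' that `SNR = 20 log10(RMS(s) / RMS(lam * ma))` equals `snr_db`:
#' `lam = RMS(s) / (RMS(ma) * 10^(snr_db / 20))`.
#'
#' @param s clean signal (`ppg_ts` or numeric).
#' @param ma artifact signal, equal length and sampling rate.
#' @param snr_db target signal-to-noise ratio in dB.
#'
#' @return A list of class `mixture_result`: `x` (the mixture, `ppg_ts`),
#'   `lam`, and the achieved `snr_db` (reproduces the request to 1e-9 dB).
#' @export
#' @examples
#' s <- ppg_ts(sin(2 * pi * seq(0, 10, 1 / 100))[-1], 100)
#' m <- ppg_ts(rnorm(length(s$samples)), 100)
#' mix_at_snr(s, m, 0)$lam
mix_at_snr <- function(s, ma, snr_db) {
  sv <- samp(s); mv <- samp(ma)
  if (length(sv) != length(mv))
    stop("`s` and `ma` must have equal length", call. = FALSE)
  fs <- fs_of(s, fs_of(ma, 1))
  if (inherits(s, "ppg_ts") && inherits(ma, "ppg_ts") && s$fs != ma$fs)
    stop("`s` and `ma` must share one sampling rate", call. = FALSE)
  rs <- sqrt(mean(sv^2)); rm_ <- sqrt(mean(mv^2))
  if (rs == 0 || rm_ == 0)
    stop("degenerate input: `s` and `ma` must have non-zero RMS", call. = FALSE)
  lam <- rs / (rm_ * 10^(snr_db / 20))
  x <- sv + lam * mv
  achieved <- 20 * log10(rs / (lam * rm_))
  stopifnot(abs(achieved - snr_db) <= 1e-9)
  structure(list(x = ppg_ts(x, fs), lam = lam, snr_db = achieved),
            class = "mixture_result")
}

#' Mix both PPG channels with one shared artifact waveform
#'
#' Adds the same artifact waveform to both channels. The artifact scale
#' `lam` is chosen so the anchor channel (default IR, the channel the
#' pipeline estimates the pulse period from) attains `snr_db` exactly;
#' the red channel receives `artifact_coupling_ratio * lam` times the
#' artifact. The default coupling ratio of 1 models probe-motion
#' artifact, which modulates the optical coupling of both wavelengths
#' alike, whereas the PPG amplitudes are wavelength-dependent — it is
#' precisely this mismatch between the artifact coupling ratio and the
#' PPG amplitude ratio that gives the two-channel observation the
#' diversity a linear unmixing needs. (Choosing per-channel scales so
#' both channels sit at the same SNR would force the coupling ratio to
#' equal the PPG amplitude ratio, making the observation rank-1 and
#' unseparable.)
#'
#' @param ppg a [two_channel_ppg()].
#' @param ma artifact `ppg_ts`, same length and rate as the channels.
#' @param snr_db target SNR in dB for the anchor channel.
#' @param artifact_coupling_ratio red/ir artifact amplitude ratio (> 0).
#' @param snr_ref_channel channel anchored at `snr_db`: `"ir"` or
#'   `"red"`.
#' @return A list with `mixture_result`s `red` and `ir` (each with its
#'   achieved `snr_db`) and the input `ma`.
#' @export
mix_two_channel <- function(ppg, ma, snr_db, artifact_coupling_ratio = 1,
                            snr_ref_channel = c("ir", "red")) {
  stopifnot(inherits(ppg, "two_channel_ppg"))
  snr_ref_channel <- match.arg(snr_ref_channel)
  if (artifact_coupling_ratio <= 0)
    stop("`artifact_coupling_ratio` must be > 0", call. = FALSE)
  anchor <- mix_at_snr(ppg[[snr_ref_channel]], ma, snr_db)
  lam_ir <- if (snr_ref_channel == "ir") anchor$lam
            else anchor$lam / artifact_coupling_ratio
  lam_red <- artifact_coupling_ratio * lam_ir
  mk <- function(ch, lam) {
    mv <- samp(ma)
    structure(list(x = ppg_ts(ch$samples + lam * mv, ch$fs), lam = lam,
                   snr_db = 20 * log10(ts_rms(ch) / (lam * sqrt(mean(mv^2))))),
              class = "mixture_result")
  }
  list(red = mk(ppg$red, lam_red), ir = mk(ppg$ir, lam_ir), ma = ma)
}

#' Relative root-mean-square error, in percent
#'
#' `RRMSE = 100 * RMS(s - s_hat) / RMS(s)`. Reports scale errors: for
#' `s_hat = a * s` the value is exactly `100 * |1 - a|`.
#'
#' @param s reference (clean) signal.
#' @param s_hat estimate, equal length.
#' @return A single non-negative percentage.
#' @export
rrmse <- function(s, s_hat) {
  sv <- samp(s); ev <- samp(s_hat)
  if (length(sv) != length(ev))
    stop("`s` and `s_hat` must have equal length", call. = FALSE)
  rs <- sqrt(mean(sv^2))
  if (rs == 0)
    stop("degenerate input: RMS(s) must be > 0", call. = FALSE)
  100 * sqrt(mean((sv - ev)^2)) / rs
}
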