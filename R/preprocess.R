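#' Design the FIR low-pass preprocessing filter
#'
#' Hamming-window FIR low-pass with passband covering the PPG band
#' (default 0--4 Hz) and at least `min_atten_db` attenuation at the
#' stopband edge (default 8 Hz). The tap count comes from the standard
#' window-method transition-width estimate and is then verified against
#' the stopband spec (and grown if needed); taps are normalized to unity
#' DC gain. The filter is intended for zero-phase application via
#' [apply_lowpass()].
#'
#' @param fs sampling rate in Hz (> 2 * `stop_hz`).
#' @param pass_hz passband edge in Hz.
#' @param stop_hz stopband edge in Hz.
#' @param min_atten_db required stopband attenuation in dB (> 0).
#'
#' @return A list of class `fir_lowpass`: `fs`, `passband_edge_hz`,
#'   `stopband_edge_hz`, `min_stop_atten_db`, `taps`.
#' @export
#' @examples
#' spec <- design_lowpass(200)
#' 20 * log10(Mod(filter_response(spec, 8)))  # <= -20
design_lowpass <- function(fs, pass_hz = 4, stop_hz = 8, min_atten_db = 20) {
  if (!is.finite(fs) || fs <= 2 * stop_hz)
    stop("`fs` must exceed twice the stopband edge", call. = FALSE)
  if (pass_hz <= 0 || pass_hz >= stop_hz)
    stop("need 0 < pass_hz < stop_hz < fs/2", call. = FALSE)
  if (min_atten_db <= 0)
    stop("`min_atten_db` must be > 0", call. = FALSE)

  trans <- (stop_hz - pass_hz) / fs       # normalized transition width
  ntaps <- ceiling(3.3 / trans)           # hamming window-method estimate
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  fc <- (pass_hz + stop_hz) / 2

  for (i in 1:8) {
    taps <- as.numeric(signal::fir1(ntaps - 1, fc / (fs / 2), type = "low",
                                    window = signal::hamming(ntaps)))
    taps <- taps / sum(taps)              # exact unity DC gain
    att <- -20 * log10(Mod(fir_response(taps, stop_hz, fs)))
    if (att >= min_atten_db) break
    ntaps <- ntaps + 2 * ceiling(0.1 * ntaps)
    if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  }
  if (att < min_atten_db)
    stop("FIR design failed to meet the stopband attenuation", call. = FALSE)

  structure(list(fs = fs, passband_edge_hz = pass_hz,
                 stopband_edge_hz = stop_hz,
                 min_stop_atten_db = min_atten_db, taps = taps),
            class = "fir_lowpass")
}

fir_response <- function(taps, f_hz, fs) {
  nvec <- seq_along(taps) - 1
  vapply(f_hz, function(f) sum(taps * exp(-2i * pi * f * nvec / fs)),
         complex(1))
}

#' Frequency response of a designed FIR filter
#'
#' Single-pass complex gain of the filter at the requested frequencies.
#' [apply_lowpass()] runs the filter forward-backward, so its effective
#' magnitude response is the square of this one (and its phase is zero).
#'
#' @param spec a `fir_lowpass` object from [design_lowpass()].
#' @param f_hz frequencies in Hz.
#' @return Complex gains, one per frequency.
#' @export
filter_response <- function(spec, f_hz) {
  stopifnot(inherits(spec, "fir_lowpass"))
  fir_response(spec$taps, f_hz, spec$fs)
}

#' Apply the FIR low-pass with zero phase
#'
#' Forward-backward application (via [signal::filtfilt()]) so waveform
#' timing is preserved; attenuation in dB is doubled relative to the
#' single-pass design.
#'
#' @param x `ppg_ts` or numeric vector.
#' @param spec a `fir_lowpass`; designed on the fly from `x`'s rate when
#'   omitted.
#' @return Filtered signal, same class and length as `x`.
#' @export
apply_lowpass <- function(x, spec = NULL) {
  fs <- fs_of(x)
  if (is.null(spec)) {
    if (is.na(fs)) stop("supply `spec` or a ppg_ts with a sampling rate",
                        call. = FALSE)
    spec <- design_lowpass(fs)
  }
  y <- reflect_pad_apply(samp(x), 3L * length(spec$taps),
                         function(v) signal::filtfilt(spec$taps, 1, v))
  if (inherits(x, "ppg_ts")) ppg_ts(y, x$fs) else y
}

# Mirror (even-reflection) padding around both ends, so zero-phase
# filters see a level-continuous signal instead of an implicit zero
# boundary; the padding is trimmed after `fun` is applied.
reflect_pad_apply <- function(v, pad, fun) {
  n <- length(v)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(fun(v))
  out <- fun(c(v[(pad + 1):2], v, v[(n - 1):(n - pad)]))
  out[(pad + 1):(pad + n)]
}

#' First-order IIR DC removal
#'
#' Applies the recursion `y(n) = x(n) - x(n-1) + pole * y(n-1)` (transfer
#' function `(1 - z^-1) / (1 - pole * z^-1)`, zero initial conditions),
#' which has exactly zero DC gain and near-unity gain over the PPG band.
#' With `zero_phase = TRUE` the recursion is run forward and then
#' backward, cancelling its phase response at the cost of squaring its
#' (near-unity in-band) magnitude response.
#'
#' @param x `ppg_ts` or numeric vector (non-empty).
#' @param pole feedback coefficient, default 0.992.
#' @param zero_phase run forward-backward instead of causally.
#' @return Same class and length as `x`.
#' @export
#' @examples
#' remove_dc(rep(1, 6))  # step input: 1, then geometric decay by 0.992
remove_dc <- function(x, pole = 0.992, zero_phase = FALSE) {
  xv <- samp(x)
  if (length(xv) < 1L) stop("`x` must be non-empty", call. = FALSE)
  run <- function(v) as.numeric(signal::filter(c(1, -1), c(1, -pole), v))
  if (zero_phase) {
    # settle both directions on reflected context (IIR time constant
    # 1 / (1 - pole) samples)
    pad <- ceiling(5 / (1 - pole))
    y <- reflect_pad_apply(xv, pad, function(v) rev(run(rev(run(v)))))
  } else {
    y <- run(xv)
  }
  if (inherits(x, "ppg_ts")) ppg_ts(y, x$fs) else y
}

#' Estimate the pulse period by autocorrelation
#'
#' Computes the biased, mean-removed autocorrelation and scores every
#' candidate lag inside the physiological band `[fs / max_hz,
#' fs / min_hz]` by the mean autocorrelation over the lag and its first
#' `n_comb` integer multiples (harmonic-comb reinforcement, the standard
#' guard against sub-harmonic and noise lags in heavily corrupted
#' records; `n_comb = 1` reduces to the plain autocorrelation argmax).
#' Ties resolve toward the shorter lag, i.e. the fundamental; the winning
#' integer lag is refined by parabolic interpolation.
#'
#' @param x `ppg_ts` (a sampling rate is required); duration must be at
#'   least `3 / min_hz` seconds.
#' @param min_hz,max_hz admissible fundamental frequency range in Hz.
#' @param n_comb number of harmonic lags averaged per candidate (>= 1).
#'
#' @return A list of class `period_estimate`: `period_samples`,
#'   `period_s`, `peak_lag_correlation` (autocorrelation at the winning
#'   lag), `search_range_samples`.
#' @export
estimate_period <- function(x, min_hz = 0.5, max_hz = 4, n_comb = 3L) {
  if (!inherits(x, "ppg_ts"))
    stop("`x` must be a ppg_ts (sampling rate required)", call. = FALSE)
  xv <- x$samples
  fs <- x$fs
  n <- length(xv)
  if (n / fs < 3 / min_hz)
    stop(sprintf("record too short: need >= %.3g s at min_hz = %g Hz",
                 3 / min_hz, min_hz), call. = FALSE)
  if (sd(xv) == 0)
    stop("degenerate input: signal has zero variance", call. = FALSE)
  lmin <- max(2L, ceiling(fs / max_hz))
  lmax <- floor(fs / min_hz)
  if (lmax >= n) stop("record too short for the requested lag range",
                      call. = FALSE)
  lag_top <- min(n - 1L, n_comb * lmax)

  r <- drop(acf(xv, lag.max = lag_top, plot = FALSE, demean = TRUE)$acf)
  score_at <- function(l) {
    ks <- seq_len(n_comb)
    ls <- ks * l
    mean(r[ls[ls <= lag_top] + 1])
  }
  cand <- lmin:lmax
  # restrict to local maxima of the autocorrelation (a lag on the
  # decaying flank of a slow-artifact acf is never a pulse period)
  is_peak <- r[cand + 1] > r[cand] & r[cand + 1] >= r[cand + 2]
  if (any(is_peak)) cand <- cand[is_peak]
  scores <- vapply(cand, score_at, numeric(1))
  # shortest candidate within 15% of the best comb score: favors the
  # fundamental over its sub-harmonics (whose combs score similarly)
  best <- max(scores)
  thr <- if (best > 0) 0.85 * best else best
  i_star <- cand[which(scores >= thr)[1]]
  # explicit half-lag check: a sub-harmonic pick scores comparably at
  # half its lag, a true fundamental does not
  half <- round(i_star / 2)
  if (half >= lmin && score_at(i_star) > 0) {
    hs <- max(lmin, half - 3L):min(lmax, half + 3L)
    h_sc <- vapply(hs, score_at, numeric(1))
    if (max(h_sc) >= 0.6 * score_at(i_star)) i_star <- hs[which.max(h_sc)]
  }

  period <- i_star
  # parabolic refinement of the comb score around the winning lag
  if (i_star > lmin && i_star < lmax) {
    sc <- score_at(i_star); sl <- score_at(i_star - 1L)
    sr <- score_at(i_star + 1L)
    denom <- sl - 2 * sc + sr
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (sl - sr) / denom
      if (abs(delta) <= 1) period <- i_star + delta
    }
  }

  structure(list(period_samples = period,
                 period_s = period / fs,
                 peak_lag_correlation = r[i_star + 1],
                 search_range_samples = c(lmin, lmax)),
            class = "period_estimate")
}

#' Periodic rectangular-pulse reference signal
#'
#' Builds the cICA reference: a pulse train with one pulse per estimated
#' period (high for `round(duty * period)` samples from each cycle onset),
#' standardized to zero mean and unit variance. The pulse polarity and
#' amplitude are irrelevant downstream: the cICA output is scale-fixed by
#' its unit-variance constraint and sign-folded against the reference.
#'
#' @param period_samples pulse period in samples (may be fractional;
#'   must satisfy `1 < period_samples < n_samples`).
#' @param n_samples output length.
#' @param duty fraction of each cycle spent high, in (0, 1).
#' @param fs sampling rate attached to the output (default 1, i.e. the
#'   reference lives on the sample index axis).
#' @param phase_samples offset of the first pulse onset, in samples
#'   (`>= 0`; see [make_aligned_reference()]).
#' @return A standardized `ppg_ts` of length `n_samples`.
#' @export
make_reference <- function(period_samples, n_samples, duty = 0.2, fs = 1,
                           phase_samples = 0) {
  if (!(period_samples > 1 && period_samples < n_samples))
    stop("need 1 < period_samples < n_samples", call. = FALSE)
  if (duty <= 0 || duty >= 1)
    stop("`duty` must lie in (0, 1)", call. = FALSE)
  if (phase_samples < 0)
    stop("`phase_samples` must be >= 0", call. = FALSE)
  high <- max(1L, round(duty * period_samples))
  x <- numeric(n_samples)
  k <- 0
  repeat {
    onset <- round(phase_samples + k * period_samples) + 1
    if (onset > n_samples) break
    x[onset:min(n_samples, onset + high - 1)] <- 1
    k <- k + 1
  }
  if (all(x == 0) || all(x == 1))
    stop("degenerate reference: pulse train is constant", call. = FALSE)
  x <- (x - mean(x)) / sd(x)
  ppg_ts(x, fs)
}

#' Rectangular reference phase-locked to the observed signal
#'
#' Builds the pulse train of [make_reference()] and chooses its phase
#' (pulse-onset offset, searched over one full period by circular
#' cross-correlation) to maximize its correlation with the supplied
#' signal — in the pipeline, the preprocessed IR channel. The artifact is
#' aperiodic, so the periodic correlation that drives the alignment comes
#' from the PPG component even in heavily corrupted records; aligning the
#' pulses with the systolic peaks makes the closeness constraint clearly
#' prefer the PPG-correlated component over the artifact.
#'
#' @param x observed `ppg_ts` the reference is aligned to.
#' @param period_samples pulse period in samples.
#' @param duty fraction of each cycle spent high, in (0, 1).
#' @return A standardized `ppg_ts`, same length and rate as `x`.
#' @export
make_aligned_reference <- function(x, period_samples, duty = 0.5) {
  if (!inherits(x, "ppg_ts"))
    stop("`x` must be a ppg_ts", call. = FALSE)
  n <- length(x$samples)
  r0 <- make_reference(period_samples, n, duty, fs = x$fs)$samples
  cc <- Re(fft(fft(x$samples) * Conj(fft(r0)), inverse = TRUE))
  shifts <- 0:(max(1L, floor(period_samples)) - 1L)
  best <- shifts[which.max(cc[shifts + 1L])]
  make_reference(period_samples, n, duty, fs = x$fs, phase_samples = best)
}
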