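# Centered moving average with shrinking windows at the edges; W odd.
moving_average <- function(x, W) {
  n <- length(x)
  h <- (W - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Frequency bands of the FFT-LMS baseline
#'
#' The FFT-LMS method treats the corrupted PPG spectrum as three parts:
#' the pulsatile PPG band (default 0.5--4 Hz), the respiratory band
#' (default 0.2--0.35 Hz), and everything else, which is taken as motion
#' artifact.
#'
#' @param pulsatile_hz,respiratory_hz frequency intervals in Hz.
#' @return A list of class `fft_lms_bands`.
#' @export
fft_lms_bands <- function(pulsatile_hz = c(0.5, 4),
                          respiratory_hz = c(0.2, 0.35)) {
  chk <- function(b, nm) {
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2])
      stop("`", nm, "` must be an increasing interval within (0, fs/2)",
           call. = FALSE)
    as.numeric(b)
  }
  structure(list(pulsatile_hz = chk(pulsatile_hz, "pulsatile_hz"),
                 respiratory_hz = chk(respiratory_hz, "respiratory_hz")),
            class = "fft_lms_bands")
}

#' Synthesize the motion-artifact reference by spectral zeroing
#'
#' Takes the full-record DFT of the corrupted signal, zeroes every bin
#' (and its negative-frequency mirror) whose frequency falls inside the
#' pulsatile or respiratory band (band edges inclusive), and inverts.
#' What remains is the motion-artifact reference used by [fft_lms()].
#' The operation is idempotent.
#'
#' @param x `ppg_ts` (sampling rate required to map bins to Hz).
#' @param bands an [fft_lms_bands()] list.
#' @return A `ppg_ts` with (numerically) no energy in the zeroed bands.
#' @export
synthesize_ma_reference <- function(x, bands = fft_lms_bands()) {
  if (!inherits(x, "ppg_ts"))
    stop("`x` must be a ppg_ts (sampling rate required)", call. = FALSE)
  if (bands$pulsatile_hz[2] > x$fs / 2 || bands$respiratory_hz[2] > x$fs / 2)
    stop("band edges must lie below fs/2", call. = FALSE)
  xv <- x$samples
  n <- length(xv)
  X <- fft(xv)
  k_half <- 0:(n %/% 2)
  f <- k_half * x$fs / n
  in_band <- (f >= bands$pulsatile_hz[1] & f <= bands$pulsatile_hz[2]) |
    (f >= bands$respiratory_hz[1] & f <= bands$respiratory_hz[2])
  kz <- k_half[in_band]
  # zero each positive-frequency bin and its negative-frequency mirror,
  # so the modified spectrum stays conjugate-symmetric (real output)
  X[c(kz, (n - kz) %% n) + 1L] <- 0
  out <- fft(X, inverse = TRUE) / n
  res_im <- max(abs(Im(out)))
  out <- Re(out)
  if (res_im > 1e-9 * max(sqrt(mean(xv^2)), 1e-300))
    stop("internal error: non-negligible imaginary residue after inverse FFT",
         call. = FALSE)
  ppg_ts(out, x$fs)
}

#' FFT-LMS baseline denoiser
#'
#' Builds the motion-artifact reference by spectral zeroing
#' ([synthesize_ma_reference()]) and feeds it to the adaptive filter
#' ([lms_fit()]) as the reference input with the corrupted signal as the
#' desired signal. The reference is artifact-correlated, so here the
#' *error* output `e` is the recovered PPG (opposite role assignment to
#' [recover_amplitude()], whose reference is PPG-correlated).
#'
#' @param x corrupted single-channel `ppg_ts`.
#' @param bands an [fft_lms_bands()] list.
#' @param params an [lms_params()] list.
#' @return A list of class `fft_lms_result`: `recovered` (`ppg_ts`),
#'   `ma_reference`, and the full `lms` result.
#' @export
fft_lms <- function(x, bands = fft_lms_bands(), params = lms_params()) {
  ref <- synthesize_ma_reference(x, bands)
  res <- lms_fit(ref, x, params)
  structure(list(recovered = res$e, ma_reference = ref, lms = res),
            class = "fft_lms_result")
}

#' Moving-average-filter baseline
#'
#' Centered moving average with an odd window of about `window_s`
#' seconds; edge samples use a shrunken window so the output length
#' equals the input length. Linear and bounded by the input range.
#'
#' @param x `ppg_ts` (sampling rate required).
#' @param window_s window length in seconds; `round(window_s * fs)`,
#'   forced odd, must stay below the record length.
#' @return Smoothed `ppg_ts`.
#' @export
maf <- function(x, window_s = 0.1) {
  if (!inherits(x, "ppg_ts"))
    stop("`x` must be a ppg_ts (sampling rate required)", call. = FALSE)
  W <- round(window_s * x$fs)
  if (W < 1 || window_s <= 0)
    stop("`window_s` must cover at least one sample", call. = FALSE)
  if (W %% 2 == 0) W <- W + 1
  if (W >= length(x$samples))
    stop("`window_s` too long for the record", call. = FALSE)
  ppg_ts(moving_average(x$samples, W), x$fs)
}
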