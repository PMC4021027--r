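#' Configuration of the full denoising pipeline
#'
#' Bundles the sub-module settings. Defaults reproduce the standard
#' 200 Hz pulse-oximeter setup: 0--4 Hz passband with 20 dB stopband
#' attenuation at 8 Hz, DC-removal pole 0.992 applied zero-phase,
#' period search over the 0.5--4 Hz pulse band, phase-aligned
#' rectangular reference with duty 0.5, multi-pass NLMS with 48 taps
#' and step 0.05.
#'
#' @param fs sampling rate in Hz.
#' @param lowpass list: `pass_hz`, `stop_hz`, `min_atten_db`.
#' @param dc_removal list: `pole`, `zero_phase`.
#' @param period list: `min_hz`, `max_hz`.
#' @param reference list: `duty`.
#' @param cica a [cica_params()] list.
#' @param lms an [lms_params()] list.
#' @param fftlms an [fft_lms_bands()] list.
#' @param maf list: `window_s`.
#' @param score_skip_transient exclude the first `lms$order` samples
#'   (the filter's zero pre-history transient) from RRMSE scoring.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 200,
                            lowpass = list(pass_hz = 4, stop_hz = 8,
                                           min_atten_db = 20),
                            dc_removal = list(pole = 0.992,
                                              zero_phase = TRUE),
                            period = list(min_hz = 0.5, max_hz = 4),
                            reference = list(duty = 0.5),
                            cica = cica_params(),
                            lms = lms_params(),
                            fftlms = fft_lms_bands(),
                            maf = list(window_s = 0.1),
                            score_skip_transient = TRUE) {
  stopifnot(fs > 0, inherits(cica, "cica_params"),
            inherits(lms, "lms_params"), inherits(fftlms, "fft_lms_bands"))
  structure(list(fs = fs, lowpass = lowpass, dc_removal = dc_removal,
                 period = period, reference = reference, cica = cica,
                 lms = lms, fftlms = fftlms, maf = maf,
                 score_skip_transient = isTRUE(score_skip_transient)),
            class = "pipeline_config")
}

#' Preprocess one channel: zero-phase low-pass plus DC removal
#'
#' The conditioning applied to each channel ahead of period estimation
#' and cICA: [apply_lowpass()] followed by [remove_dc()] with the
#' settings in `cfg`.
#'
#' @param x `ppg_ts`.
#' @param cfg a [pipeline_config()].
#' @param fir optionally a pre-designed `fir_lowpass` (saves the design
#'   when processing many channels).
#' @return Preprocessed `ppg_ts`.
#' @export
preprocess_channel <- function(x, cfg = pipeline_config(), fir = NULL) {
  if (is.null(fir))
    fir <- design_lowpass(cfg$fs, cfg$lowpass$pass_hz, cfg$lowpass$stop_hz,
                          cfg$lowpass$min_atten_db)
  y <- apply_lowpass(x, fir)
  remove_dc(y, pole = cfg$dc_removal$pole,
            zero_phase = isTRUE(cfg$dc_removal$zero_phase))
}

#' Full cICA-LMS motion-artifact removal
#'
#' Runs the four-step method on a two-channel observation:
#' (a) zero-phase FIR low-pass and DC removal on both channels;
#' (b) autocorrelation period estimation on the IR channel and
#' rectangular-reference generation; (c) constrained-ICA extraction of
#' the PPG-correlated component from the two preprocessed channels;
#' (d) per-channel LMS amplitude recovery with that component as the
#' reference. If the cICA iteration fails to converge the result carries
#' `cica$converged = FALSE` and recovery is still attempted.
#'
#' @param ppg a [two_channel_ppg()] of at least 10 s.
#' @param cfg a [pipeline_config()]; its `fs` must match the data.
#'
#' @return A list of class `denoise_output`: per-channel `recovered_*`
#'   and `ma_estimate_*` (`recovered + ma_estimate` equals the
#'   preprocessed channel exactly), the `cica` result, the `period`
#'   estimate, the `reference`, and the `preprocessed` channels.
#' @export
denoise_cica_lms <- function(ppg, cfg = pipeline_config()) {
  stopifnot(inherits(ppg, "two_channel_ppg"))
  if (!isTRUE(all.equal(ppg$ir$fs, cfg$fs)))
    stop("`cfg$fs` does not match the data", call. = FALSE)
  n <- length(ppg$ir$samples)
  if (n / cfg$fs < 10)
    stop("both channels must be at least 10 s long", call. = FALSE)

  fir <- design_lowpass(cfg$fs, cfg$lowpass$pass_hz, cfg$lowpass$stop_hz,
                        cfg$lowpass$min_atten_db)
  pre_red <- preprocess_channel(ppg$red, cfg, fir)
  pre_ir <- preprocess_channel(ppg$ir, cfg, fir)

  period <- estimate_period(pre_ir, cfg$period$min_hz, cfg$period$max_hz)
  ref <- make_aligned_reference(pre_ir, period$period_samples,
                                cfg$reference$duty)

  cres <- extract_component(two_channel_ppg(pre_red, pre_ir), ref, cfg$cica)

  rec_red <- recover_amplitude(pre_red, cres$y, cfg$lms)
  rec_ir <- recover_amplitude(pre_ir, cres$y, cfg$lms)

  structure(list(recovered_red = rec_red$recovered_ppg,
                 recovered_ir = rec_ir$recovered_ppg,
                 ma_estimate_red = rec_red$ma_estimate,
                 ma_estimate_ir = rec_ir$ma_estimate,
                 cica = cres, period = period, reference = ref,
                 preprocessed = list(red = pre_red, ir = pre_ir)),
            class = "denoise_output")
}

#' Single-channel denoising dispatcher
#'
#' Applies one of the baseline methods to a single corrupted channel:
#' `"fft_lms"` or `"maf"`. (The cICA-LMS method needs both channels; use
#' [denoise_cica_lms()].)
#'
#' @param x corrupted `ppg_ts`.
#' @param method `"fft_lms"` or `"maf"`.
#' @param cfg a [pipeline_config()].
#' @return The recovered `ppg_ts`.
#' @export
denoise_channel <- function(x, method = c("fft_lms", "maf"),
                            cfg = pipeline_config()) {
  method <- match.arg(method)
  switch(method,
         fft_lms = fft_lms(x, cfg$fftlms, cfg$lms)$recovered,
         maf = maf(x, cfg$maf$window_s))
}

#' Per-cycle peak-to-peak statistics
#'
#' Segments the signal into consecutive windows of one estimated period
#' and reports the mean and standard deviation of the per-window
#' `max - min` — the quantity whose preservation matters for the
#' ratio-of-ratios SpO2 computation.
#'
#' @param x `ppg_ts` or numeric vector covering at least two full
#'   periods.
#' @param period a `period_estimate` (or a number of samples).
#' @return A list of class `peak_to_peak_stats`: `mean`, `sd`,
#'   `n_cycles`.
#' @export
peak_to_peak_stats <- function(x, period) {
  xv <- samp(x)
  p <- if (inherits(period, "period_estimate")) period$period_samples
       else as.numeric(period)
  p_int <- round(p)
  if (p_int < 2) stop("period too short", call. = FALSE)
  n_cycles <- floor(length(xv) / p_int)
  if (n_cycles < 2)
    stop("need at least two full periods", call. = FALSE)
  vals <- vapply(seq_len(n_cycles), function(k) {
    seg <- xv[((k - 1) * p_int + 1):(k * p_int)]
    max(seg) - min(seg)
  }, numeric(1))
  structure(list(mean = mean(vals), sd = sd(vals),
                 n_cycles = as.integer(n_cycles)),
            class = "peak_to_peak_stats")
}
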