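#' Uniformly sampled time series
#'
#' The basic container used throughout the package: a numeric vector of
#' samples together with its sampling rate in Hz. All signal operations
#' (`remove_dc()`, `lms()`, `rrmse()`, ...) accept and return `ppg_ts`
#' objects; plain numeric vectors are accepted wherever the sampling rate
#' is irrelevant or supplied separately.
#'
#' @param samples numeric vector of finite sample values (length >= 1).
#' @param fs sampling rate in Hz (single positive number).
#'
#' @return An object of class `ppg_ts`: a list with elements `samples`
#'   and `fs`.
#' @export
#' @examples
#' x <- ppg_ts(sin(2 * pi * 1.25 * seq(0, 10, by = 1 / 200)), fs = 200)
#' x
ppg_ts <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("`samples` must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all `samples` must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs)), class = "ppg_ts")
}

#' @export
print.ppg_ts <- function(x, ...) {
  cat(sprintf("<ppg_ts> %d samples at %g Hz (%.3g s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ppg_ts <- function(x) length(x$samples)

# Extract the raw sample vector from a ppg_ts or numeric input.
samp <- function(x) {
  if (inherits(x, "ppg_ts")) x$samples else as.numeric(x)
}

# Sampling rate, with fallback when the input is a bare vector.
fs_of <- function(x, default = NA_real_) {
  if (inherits(x, "ppg_ts")) x$fs else default
}

#' Root-mean-square of a signal
#'
#' Uncorrected RMS over the full record: `sqrt(mean(x^2))`. No detrending
#' is applied; this is the quantity entering the SNR and RRMSE definitions.
#'
#' @param x a `ppg_ts` or numeric vector.
#' @return A single non-negative number.
#' @export
ts_rms <- function(x) {
  sqrt(mean(samp(x)^2))
}

#' Paired red/infrared PPG channels
#'
#' Container for a two-channel PPG observation: the red and infrared
#' channels must have equal length and equal sampling rate.
#'
#' @param red,ir `ppg_ts` objects (or numeric vectors, with `fs` supplied).
#' @param fs sampling rate in Hz, required when `red`/`ir` are bare vectors.
#'
#' @return An object of class `two_channel_ppg`: list with `red`, `ir`.
#' @export
two_channel_ppg <- function(red, ir, fs = NULL) {
  if (!inherits(red, "ppg_ts")) red <- ppg_ts(red, fs)
  if (!inherits(ir, "ppg_ts")) ir <- ppg_ts(ir, fs)
  if (length(red$samples) != length(ir$samples))
    stop("red and ir channels must have equal length", call. = FALSE)
  if (red$fs != ir$fs)
    stop("red and ir channels must share one sampling rate", call. = FALSE)
  structure(list(red = red, ir = ir), class = "two_channel_ppg")
}

#' @export
print.two_channel_ppg <- function(x, ...) {
  cat(sprintf("<two_channel_ppg> %d samples x 2 channels at %g Hz\n",
              length(x$red$samples), x$red$fs))
  invisible(x)
}

# 2 x N channel matrix (red on top), for whitening / ICA.
channel_matrix <- function(x) {
  stopifnot(inherits(x, "two_channel_ppg"))
  rbind(red = x$red$samples, ir = x$ir$samples)
}
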