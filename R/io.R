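#' Read a PPG recording from delimited text
#'
#' Expects a header row and either columns `t, red, ir` (two-channel) or
#' `t, signal` (single channel); comma- or tab-delimited. The sampling
#' rate is inferred from the median spacing of `t` unless given
#' explicitly; an explicit `fs` wins, but a disagreement with the time
#' axis of more than 0.1% is an error.
#'
#' @param path file path.
#' @param fs optional explicit sampling rate in Hz.
#' @return A [two_channel_ppg()] or a `ppg_ts`, depending on columns.
#' @export
read_ppg_csv <- function(path, fs = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, header = TRUE)
  nm <- tolower(names(df))
  if (!"t" %in% nm)
    stop("input must have a `t` column", call. = FALSE)
  t <- df[[which(nm == "t")]]
  if (length(t) < 2)
    stop("need at least two samples", call. = FALSE)
  fs_inferred <- 1 / stats::median(diff(t))
  if (is.null(fs)) {
    fs <- fs_inferred
  } else if (abs(fs - fs_inferred) > 0.001 * fs_inferred) {
    stop(sprintf("explicit fs = %g Hz disagrees with the time axis (%g Hz) by more than 0.1%%",
                 fs, fs_inferred), call. = FALSE)
  }
  if (all(c("red", "ir") %in% nm)) {
    two_channel_ppg(ppg_ts(df[[which(nm == "red")]], fs),
                    ppg_ts(df[[which(nm == "ir")]], fs))
  } else if ("signal" %in% nm) {
    ppg_ts(df[[which(nm == "signal")]], fs)
  } else {
    stop("input must have columns `t,red,ir` or `t,signal`", call. = FALSE)
  }
}

#' Write a PPG recording as CSV
#'
#' Writes `t,red,ir` for a [two_channel_ppg()] or `t,signal` for a
#' `ppg_ts`, with the time axis derived from the sampling rate.
#'
#' @param x a `two_channel_ppg` or `ppg_ts`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppg_csv <- function(x, path) {
  if (inherits(x, "two_channel_ppg")) {
    n <- length(x$red$samples)
    df <- data.frame(t = (seq_len(n) - 1) / x$red$fs,
                     red = x$red$samples, ir = x$ir$samples)
  } else if (inherits(x, "ppg_ts")) {
    df <- data.frame(t = (seq_along(x$samples) - 1) / x$fs,
                     signal = x$samples)
  } else {
    stop("`x` must be a two_channel_ppg or ppg_ts", call. = FALSE)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
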