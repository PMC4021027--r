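#' Parameters of the LMS adaptive filter
#'
#' @param order number of taps `L` (>= 1).
#' @param mu step size (>= 0; `mu = 0` freezes the taps at `w_init`).
#'   With `normalize_mu = TRUE` (NLMS, the default) the effective
#'   per-sample step is `mu / (L * P(n) + delta)`, where `P(n)` is an
#'   exponentially smoothed input-power estimate, making `mu` unit-free
#'   and the recursion stable for `mu <= 1`. Plain LMS
#'   (`normalize_mu = FALSE`) uses `mu` directly.
#' @param normalize_mu logical; normalize the step by the smoothed input
#'   power.
#' @param w_init initial tap vector (length `order`) or `NULL` for zeros.
#' @param delta small regularizer in the NLMS denominator.
#' @param power_smoothing forgetting weight `beta` of the power estimate
#'   `P(n) = (1 - beta) P(n-1) + beta u(n)^2` (initialized at the
#'   record's mean power). Smoothing keeps the normalized step bounded
#'   where a periodic reference crosses zero.
#' @param passes number of adaptation sweeps over the record taken by
#'   [lms_fit()] (ignored by the single-pass [lms()]).
#' @param average_taps logical; have [lms_fit()] refilter with the
#'   Polyak (running) average of the taps over the final sweep rather
#'   than their last value.
#' @param keep_trace keep the full per-sample tap trajectory (order x n
#'   matrix) in the result.
#' @return A list of class `lms_params`.
#' @export
lms_params <- function(order = 48L, mu = 0.05, normalize_mu = TRUE,
                       w_init = NULL, delta = 1e-8,
                       power_smoothing = 0.01, passes = 12L,
                       average_taps = TRUE, keep_trace = FALSE) {
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (!is.finite(mu) || mu < 0)
    stop("`mu` must be a non-negative number", call. = FALSE)
  if (!is.null(w_init) && length(w_init) != order)
    stop("`w_init` must have length `order`", call. = FALSE)
  if (power_smoothing <= 0 || power_smoothing > 1)
    stop("`power_smoothing` must lie in (0, 1]", call. = FALSE)
  if (passes < 1) stop("`passes` must be >= 1", call. = FALSE)
  structure(list(order = as.integer(order), mu = mu,
                 normalize_mu = isTRUE(normalize_mu),
                 w_init = w_init, delta = delta,
                 power_smoothing = power_smoothing,
                 passes = as.integer(passes),
                 average_taps = isTRUE(average_taps),
                 keep_trace = isTRUE(keep_trace)),
            class = "lms_params")
}

run_lms_core <- function(uv, dv, params, w0, mu = params$mu) {
  lms_core(uv, dv, params$order, mu, params$normalize_mu, w0,
           params$delta, params$power_smoothing, mean(uv^2),
           params$keep_trace)
}

wrap_lms_result <- function(res, params, fs) {
  wrap <- function(v) if (is.na(fs)) v else ppg_ts(v, fs)
  structure(list(y = wrap(res$y), e = wrap(res$e),
                 w_final = res$w_final,
                 w_trace = if (params$keep_trace) res$w_trace else NULL,
                 diverged = res$diverged),
            class = "lms_result")
}

#' LMS adaptive filtering (single pass)
#'
#' Implements the three-line LMS recursion with a tapped-delay-line input
#' (zero pre-history): `y(n) = w(n)' u(n)`, `e(n) = d(n) - y(n)`,
#' `w(n+1) = w(n) + mu e(n) u(n)`. The decomposition `d = y + e` holds at
#' every sample by construction. A divergence flag is raised if the tap
#' norm exceeds 1e6 times its initial scale.
#'
#' @param u filter (reference) input, `ppg_ts` or numeric.
#' @param d desired signal, equal length.
#' @param params an [lms_params()] list.
#'
#' @return A list of class `lms_result`: `y`, `e` (same class as the
#'   inputs), `w_final`, `w_trace` (`NULL` unless requested), `diverged`.
#' @export
#' @examples
#' u <- rnorm(2000)
#' res <- lms(u, 0.5 * u, lms_params(order = 1, mu = 0.2))
#' res$w_final  # ~0.5
lms <- function(u, d, params = lms_params()) {
  uv <- samp(u); dv <- samp(d)
  if (length(uv) != length(dv))
    stop("`u` and `d` must have equal length", call. = FALSE)
  if (params$order >= length(uv))
    stop("`order` must be smaller than the signal length", call. = FALSE)
  w0 <- if (is.null(params$w_init)) numeric(params$order) else
    as.numeric(params$w_init)
  res <- run_lms_core(uv, dv, params, w0)
  wrap_lms_result(res, params, fs_of(u, fs_of(d)))
}

#' Multi-pass LMS fit with frozen-tap evaluation
#'
#' Offline variant for block processing of whole records: the LMS
#' recursion of [lms()] is swept over the record `passes` times (each
#' sweep continuing from the previous taps) to converge the taps, and
#' the record is then refiltered once with the taps frozen — by default
#' at their running (Polyak) average over the final sweep, which
#' suppresses the stochastic tap jitter that adaptation noise induces
#' when the interference in `d` is strong and autocorrelated. The
#' returned `y`/`e` come from the frozen pass, so `y` is a static FIR
#' function of `u` and `d = y + e` still holds exactly.
#'
#' @inheritParams lms
#' @return An `lms_result` (see [lms()]); `w_final` holds the frozen
#'   taps used for the evaluation pass.
#' @export
lms_fit <- function(u, d, params = lms_params()) {
  uv <- samp(u); dv <- samp(d)
  if (length(uv) != length(dv))
    stop("`u` and `d` must have equal length", call. = FALSE)
  if (params$order >= length(uv))
    stop("`order` must be smaller than the signal length", call. = FALSE)
  w <- if (is.null(params$w_init)) numeric(params$order) else
    as.numeric(params$w_init)
  diverged <- FALSE
  for (p in seq_len(params$passes)) {
    res <- run_lms_core(uv, dv, params, w)
    diverged <- diverged || res$diverged
    w <- res$w_final
  }
  w_frozen <- if (params$average_taps) res$w_avg else res$w_final
  final <- run_lms_core(uv, dv, params, w_frozen, mu = 0)
  out <- wrap_lms_result(final, params, fs_of(u, fs_of(d)))
  out$w_final <- w_frozen
  out$diverged <- diverged
  out
}

#' Restore channel amplitude to the unit-variance cICA component
#'
#' Runs the adaptive filter with the standardized PPG-correlated
#' component as the reference input `u` and the corrupted channel as the
#' desired signal `d` (via [lms_fit()]). Because the reference is
#' PPG-correlated, the filter output `y` is the PPG part of the channel
#' at the channel's own scale (the recovered PPG), and the error `e` is
#' the motion-artifact estimate; `recovered + ma_estimate` reconstructs
#' the input exactly. The taps absorb the component's sign, so a
#' sign-flipped reference yields the same recovered signal.
#'
#' @param corrupted the (preprocessed) corrupted channel.
#' @param ppg_component standardized cICA output, equal length.
#' @param params an [lms_params()] list.
#' @return A list: `recovered_ppg`, `ma_estimate`, and the full `lms`
#'   result.
#' @export
recover_amplitude <- function(corrupted, ppg_component,
                              params = lms_params()) {
  res <- lms_fit(ppg_component, corrupted, params)
  list(recovered_ppg = res$y, ma_estimate = res$e, lms = res)
}
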