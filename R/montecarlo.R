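#' Monte-Carlo RRMSE evaluation over an SNR grid
#'
#' For each replicate, draws a fresh synthetic two-channel clean PPG
#' (heart rate uniform over `hr_range_hz`) and a fresh artifact, mixes
#' both channels with the shared artifact waveform at each SNR of the
#' grid (channel-specific scale so each channel attains the target SNR),
#' runs the requested methods, and scores each channel's recovery
#' against the clean signal with [rrmse()]. The same replicate draws are
#' reused across the SNR grid (common random numbers), so method curves
#' are compared on identical inputs. Method failures are recorded and
#' skipped, not fatal.
#'
#' @param cfg a [pipeline_config()].
#' @param snr_grid SNR levels in dB (within `[-30, 30]`); default the
#'   standard -10..10 dB sweep with 1 dB steps.
#' @param n_reps replicates per SNR level (>= 1).
#' @param methods subset of `c("cica_lms", "fft_lms", "maf")`.
#' @param master_seed integer seed; the whole table is reproducible from
#'   it.
#' @param duration_s record length per replicate, seconds.
#' @param hr_range_hz heart-rate sampling range in Hz.
#' @param artifact_model artifact model for the replicates.
#'
#' @return A data frame of class `evaluation_table` with columns
#'   `method`, `snr_db`, `channel`, `mean_rrmse_pct`, `sd_rrmse_pct`,
#'   `n_reps` (replicates that scored). Per-replicate scores are kept in
#'   attribute `"details"`; failures (if any) in attribute `"failures"`.
#' @export
monte_carlo <- function(cfg = pipeline_config(),
                        snr_grid = seq(-10, 10, by = 1),
                        n_reps = 30L,
                        methods = c("cica_lms", "fft_lms", "maf"),
                        master_seed = 1L,
                        duration_s = 20,
                        hr_range_hz = c(1.0, 1.7),
                        artifact_model = "composite") {
  stopifnot(n_reps >= 1, all(snr_grid >= -30 & snr_grid <= 30))
  methods <- match.arg(methods, several.ok = TRUE)
  skip <- if (cfg$score_skip_transient) cfg$lms$order else 0L

  draws <- with_seed(master_seed, {
    data.frame(rep = seq_len(n_reps),
               hr = runif(n_reps, hr_range_hz[1], hr_range_hz[2]),
               ppg_seed = sample.int(2^31 - 2, n_reps),
               ma_seed = sample.int(2^31 - 2, n_reps))
  })

  score <- function(clean, est) {
    idx <- (skip + 1):length(clean$samples)
    rrmse(clean$samples[idx], samp(est)[idx])
  }

  details <- vector("list", n_reps * length(snr_grid))
  failures <- list()
  row_i <- 0L
  for (r in seq_len(n_reps)) {
    ppg <- generate_clean_ppg(ppg_model_params(
      heart_rate_hz = draws$hr[r], duration_s = duration_s, fs = cfg$fs,
      seed = draws$ppg_seed[r]))
    ma <- generate_artifact(artifact_model_params(
      model = artifact_model, duration_s = duration_s, fs = cfg$fs,
      seed = draws$ma_seed[r]))
    for (snr in snr_grid) {
      mx <- mix_two_channel(ppg, ma, snr)
      corrupted <- two_channel_ppg(mx$red$x, mx$ir$x)
      for (m in methods) {
        est <- tryCatch(
          switch(m,
            cica_lms = {
              out <- denoise_cica_lms(corrupted, cfg)
              list(red = out$recovered_red, ir = out$recovered_ir)
            },
            fft_lms = list(
              red = fft_lms(corrupted$red, cfg$fftlms, cfg$lms)$recovered,
              ir = fft_lms(corrupted$ir, cfg$fftlms, cfg$lms)$recovered),
            maf = list(red = maf(corrupted$red, cfg$maf$window_s),
                       ir = maf(corrupted$ir, cfg$maf$window_s))),
          error = function(e) e)
        if (inherits(est, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(method = m, snr_db = snr, rep = r,
                       reason = conditionMessage(est))
          next
        }
        row_i <- row_i + 1L
        details[[row_i]] <- data.frame(
          method = m, snr_db = snr, rep = r,
          channel = c("red", "ir"),
          rrmse_pct = c(score(ppg$red, est$red), score(ppg$ir, est$ir)))
      }
    }
  }
  details <- do.call(rbind, details[seq_len(row_i)])

  agg <- do.call(rbind, lapply(
    split(details, details[c("method", "snr_db", "channel")], drop = TRUE),
    function(d) data.frame(method = d$method[1], snr_db = d$snr_db[1],
                           channel = d$channel[1],
                           mean_rrmse_pct = mean(d$rrmse_pct),
                           sd_rrmse_pct = if (nrow(d) > 1) sd(d$rrmse_pct)
                                          else 0,
                           n_reps = nrow(d))))
  agg <- agg[order(agg$method, agg$snr_db, agg$channel), ]
  rownames(agg) <- NULL
  attr(agg, "details") <- details
  attr(agg, "failures") <- if (length(failures)) do.call(rbind, failures)
                           else NULL
  class(agg) <- c("evaluation_table", class(agg))
  agg
}
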