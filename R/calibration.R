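#' Simulate per-participant window-mean amplitude estimates
#'
#' Draws one cohort of per-participant error-minus-hit window mean
#' amplitudes the way the full chain would measure them, using the same
#' noise generator and component shapes, but computing the window means
#' directly at the epoch level. Because window averaging, baseline
#' correction and epoch averaging are all linear and every epoch shares the
#' release offset, the participant's difference-wave window mean equals
#' (mean over error epochs - mean over hit epochs) of per-epoch
#' baseline-corrected window means exactly; this identity is covered by a
#' unit test against the full pipeline.
#'
#' @param n_participants cohort size.
#' @param n_error,n_hit clear-error / clear-hit epochs per participant.
#' @param peak_amplitude design-point peak amplitude (microvolts) of the
#'   injected release-locked component (Ne/ERN-like, window 200-350 ms).
#' @param between_sd SD of per-participant true peaks around the design
#'   point.
#' @param noise noise parameters, see [generate_noise()].
#' @param fs sampling rate (Hz).
#' @param windows an [analysis_windows()].
#' @param epoch_window_ms epoch span (ms relative to release) over which
#'   noise epochs are generated.
#' @return numeric vector: one window-mean amplitude per participant.
#' @export
simulate_cohort_amplitudes <- function(n_participants = 18, n_error = 8,
                                       n_hit = 8, peak_amplitude = 0,
                                       between_sd = 0,
                                       noise = list(pink_sd = 8, white_sd = 3,
                                                    alpha = 1,
                                                    f_floor = 0.25),
                                       fs = 500,
                                       windows = analysis_windows(),
                                       epoch_window_ms = c(-100, 600)) {
  comp <- erp_component("release", windows$effw_ern,
                        peak_amplitude = 1)  # unit shape, scaled below
  k0 <- round(epoch_window_ms[1] / 1000 * fs)
  k1 <- round(epoch_window_ms[2] / 1000 * fs)
  times_ms <- (k0:k1) / fs * 1000
  sel_base <- window_sample_index(times_ms, windows$baseline)
  sel_win <- window_sample_index(times_ms, windows$effw_ern)
  shape_mean <- mean(component_waveform(comp, times_ms[sel_win]))
  n_ep <- n_error + n_hit
  vapply(seq_len(n_participants), function(p) {
    amp <- peak_amplitude + if (between_sd > 0) rnorm(1, 0, between_sd) else 0
    nm <- generate_noise_matrix(length(times_ms), n_ep, fs = fs,
                                pink_sd = noise$pink_sd,
                                white_sd = noise$white_sd,
                                alpha = noise$alpha,
                                f_floor = noise$f_floor)
    wm <- colMeans(nm[sel_win, , drop = FALSE]) -
      colMeans(nm[sel_base, , drop = FALSE])
    wm[seq_len(n_error)] <- wm[seq_len(n_error)] + amp * shape_mean
    mean(wm[seq_len(n_error)]) - mean(wm[n_error + seq_len(n_hit)])
  }, 0)
}

#' Monte-Carlo calibration study of the group-level test
#'
#' Repeats [simulate_cohort_amplitudes()] over many cohorts and applies the
#' directional one-sample t-test to each, returning per-cohort estimates,
#' t statistics and p-values. With `peak_amplitude = 0` this measures the
#' empirical type-I error rate of the test; with a nonzero design point it
#' measures power and estimator bias.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param tail test tail, default `"negative"`.
#' @param alpha nominal significance level.
#' @inheritParams simulate_cohort_amplitudes
#' @return data.frame with one row per cohort: `estimate`, `t`, `p`,
#'   `reject`.
#' @export
simulate_calibration_study <- function(n_cohorts = 1000, n_participants = 18,
                                       n_error = 8, n_hit = 8,
                                       peak_amplitude = 0, between_sd = 0,
                                       noise = list(pink_sd = 8, white_sd = 3,
                                                    alpha = 1,
                                                    f_floor = 0.25),
                                       fs = 500,
                                       windows = analysis_windows(),
                                       tail = "negative", alpha = 0.05) {
  rows <- vapply(seq_len(n_cohorts), function(i) {
    vals <- simulate_cohort_amplitudes(n_participants, n_error, n_hit,
                                       peak_amplitude, between_sd, noise,
                                       fs, windows)
    res <- one_sample_t(vals, tail = tail)
    c(res$estimate, res$t, res$p)
  }, numeric(3))
  out <- data.frame(estimate = rows[1, ], t = rows[2, ], p = rows[3, ])
  out$reject <- out$p < alpha
  out
}
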