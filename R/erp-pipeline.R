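#' Analysis windows for the difference-wave statistics
#'
#' The a priori windows of the task: baseline 0-200 ms after ball release
#' (the interval between release and the Ne/ERN effect window), Ne/ERN
#' effect window 200-350 ms after ball release, FRN effect window 150-350 ms
#' after outcome feedback. All windows are half-open `[start, end)` on the
#' sample grid.
#'
#' @param baseline,effw_ern length-2 ms windows relative to ball release.
#' @param effw_frn length-2 ms window relative to feedback onset.
#' @return An object of class `sk_windows`.
#' @export
analysis_windows <- function(baseline = c(0, 200), effw_ern = c(200, 350),
                             effw_frn = c(150, 350)) {
  for (w in list(baseline, effw_ern, effw_frn))
    if (length(w) != 2 || w[1] >= w[2])
      stop("windows must be (start, end) with start < end", call. = FALSE)
  structure(list(baseline = baseline, effw_ern = effw_ern,
                 effw_frn = effw_frn), class = "sk_windows")
}

#' Band-pass filter and re-reference a recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass per channel
#' and, optionally, re-references every scalp channel to the average of the
#' two mastoids. Defaults: 0.2-30 Hz, order 2. Pass `filter = NULL` to skip
#' filtering (e.g. for noise-free validation runs where the passband shaping
#' of the filter is not under study).
#'
#' @param recording an `sk_recording`.
#' @param filter list with `low`, `high` (Hz) and `order`, or `NULL`.
#' @param reference `"linked_mastoids"` or `"none"`.
#' @param mastoids the two mastoid channel labels.
#' @return the preprocessed `sk_recording`.
#' @export
preprocess <- function(recording,
                       filter = list(low = 0.2, high = 30, order = 2),
                       reference = c("linked_mastoids", "none"),
                       mastoids = c("M1", "M2")) {
  reference <- match.arg(reference)
  x <- recording$samples
  if (reference == "linked_mastoids") {
    if (!all(mastoids %in% recording$channels))
      stop("configuration error: mastoid channels ",
           paste(mastoids, collapse = "/"), " not present", call. = FALSE)
    ref <- rowMeans(x[, mastoids, drop = FALSE])
    scalp <- setdiff(recording$channels, mastoids)
    x[, scalp] <- x[, scalp] - ref
    x[, mastoids] <- x[, mastoids] - ref
  }
  if (!is.null(filter)) {
    nyq <- recording$fs / 2
    if (!(filter$low > 0 && filter$low < filter$high && filter$high < nyq))
      stop("filter cutoffs must satisfy 0 < low < high < Nyquist",
           call. = FALSE)
    bf <- signal::butter(filter$order, c(filter$low, filter$high) / nyq,
                         type = "pass")
    for (j in seq_len(ncol(x)))
      x[, j] <- signal::filtfilt(bf, x[, j])
  }
  recording$samples <- x
  recording
}

#' Segmentation specification
#'
#' Condition-specific epoch windows: the observation (`Visual`) condition is
#' anchored at trial start and spans -600 to +2800 ms (covering trial start,
#' observed release, and feedback); the active (`EffProp`) condition is
#' anchored at ball release and spans -600 to +2200 ms.
#'
#' @param condition `"Visual"` or `"EffProp"`.
#' @param anchor_event,start_offset_ms,end_offset_ms overrides.
#' @return An object of class `sk_segmentspec`.
#' @export
segment_spec <- function(condition = c("EffProp", "Visual"),
                         anchor_event = NULL, start_offset_ms = NULL,
                         end_offset_ms = NULL) {
  condition <- match.arg(condition)
  def <- if (condition == "Visual")
    list(anchor = "S_trialstart", start = -600, end = 2800)
  else
    list(anchor = "S_release", start = -600, end = 2200)
  structure(list(condition = condition,
                 anchor_event = anchor_event %||% def$anchor,
                 start_offset_ms = start_offset_ms %||% def$start,
                 end_offset_ms = end_offset_ms %||% def$end),
            class = "sk_segmentspec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut event-locked epochs from a continuous recording
#'
#' One epoch per trial whose `erp_class` is not `"excluded"`. Epochs are cut
#' around the spec's anchor marker; the per-epoch release and feedback
#' marker offsets (samples relative to the anchor) are stored so that window
#' math downstream is marker-relative even when, as in the observation
#' condition, the release latency varies from trial to trial. Epochs that
#' would overlap a recording edge are dropped and counted in
#' `$n_dropped_edge`.
#'
#' @param recording a preprocessed `sk_recording`.
#' @param trials the matching trial table.
#' @param spec an [segment_spec()].
#' @return An object of class `sk_epochs`: `data` (epoch x time x channel
#'   array), `times_ms` (anchor-relative), `channels`, `fs`, `info`
#'   (per-epoch trial id, outcome, erp class, release/feedback offsets in
#'   samples, rejection flag), `anchor`, `n_dropped_edge`.
#' @export
segment_epochs <- function(recording, trials, spec = segment_spec()) {
  fs <- recording$fs
  mk <- recording$markers
  keep <- trials[trials$erp_class != "excluded", , drop = FALSE]
  if (nrow(keep) == 0) stop("no non-excluded trials to segment",
                            call. = FALSE)
  find_marker <- function(type, id) {
    s <- mk$sample[mk$type == type & mk$trial_id == id]
    if (length(s) != 1)
      stop("consistency error: expected exactly one ", type,
           " marker for trial ", id, call. = FALSE)
    s
  }
  k0 <- round(spec$start_offset_ms / 1000 * fs)
  k1 <- round(spec$end_offset_ms / 1000 * fs)
  times_ms <- (k0:k1) / fs * 1000
  nt <- length(times_ms)
  nch <- length(recording$channels)
  n <- nrow(recording$samples)
  data_list <- list(); info_list <- list(); dropped <- 0L
  for (r in seq_len(nrow(keep))) {
    id <- keep$trial_id[r]
    anchor <- find_marker(spec$anchor_event, id)
    rel <- find_marker("S_release", id)
    fb <- find_marker("S_feedback", id)
    lo <- anchor + k0; hi <- anchor + k1
    if (lo < 1L || hi > n) { dropped <- dropped + 1L; next }
    data_list[[length(data_list) + 1L]] <-
      recording$samples[lo:hi, , drop = FALSE]
    info_list[[length(info_list) + 1L]] <- data.frame(
      trial_id = id, outcome = keep$outcome[r],
      erp_class = keep$erp_class[r],
      release_offset = rel - anchor, feedback_offset = fb - anchor,
      rejected = FALSE)
  }
  if (!length(data_list))
    stop("all epochs overlap recording edges", call. = FALSE)
  if (dropped > 0)
    message(dropped, " epoch(s) dropped at recording edges")
  data <- array(0, dim = c(length(data_list), nt, nch),
                dimnames = list(NULL, NULL, recording$channels))
  for (e in seq_along(data_list)) data[e, , ] <- data_list[[e]]
  structure(list(data = data, times_ms = times_ms,
                 channels = recording$channels, fs = fs,
                 info = do.call(rbind, info_list), anchor = spec$anchor_event,
                 participant_id = recording$participant_id,
                 condition = recording$condition,
                 n_dropped_edge = dropped),
            class = "sk_epochs")
}

#' Amplitude-threshold artifact rejection
#'
#' Automated stand-in for manual artifact control: an epoch is flagged
#' rejected when any sample on any channel exceeds `threshold` in absolute
#' value.
#'
#' @param epochs an `sk_epochs`.
#' @param threshold microvolts, > 0. Default 100.
#' @return the `sk_epochs` with updated rejection flags; rejected epochs are
#'   kept in the object but ignored by [outcome_averages()].
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  nep <- dim(epochs$data)[1]
  rej <- vapply(seq_len(nep), function(e)
    max(abs(epochs$data[e, , ])) > threshold, logical(1))
  epochs$info$rejected <- rej
  if (any(rej)) message(sum(rej), " epoch(s) rejected at +/-", threshold,
                        " microvolts")
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default 0-200 ms after the epoch's own ball-release marker) from the
#' whole epoch. The single release-locked baseline is used for the entire
#' epoch, including feedback-locked analysis.
#'
#' @param epochs an `sk_epochs`.
#' @param windows an [analysis_windows()].
#' @return the corrected `sk_epochs`.
#' @export
baseline_correct <- function(epochs, windows = analysis_windows()) {
  fs <- epochs$fs
  step_ms <- 1000 / fs
  for (e in seq_len(dim(epochs$data)[1])) {
    off_ms <- epochs$info$release_offset[e] * step_ms
    sel <- window_sample_index(epochs$times_ms,
                               windows$baseline + off_ms)
    if (!length(sel))
      stop("window error: baseline outside epoch span", call. = FALSE)
    for (ch in seq_len(dim(epochs$data)[3]))
      epochs$data[e, , ch] <- epochs$data[e, , ch] -
        mean(epochs$data[e, sel, ch])
  }
  epochs
}

# half-open [start, end) window on the sample grid
window_sample_index <- function(times_ms, window_ms) {
  which(times_ms >= window_ms[1] - 1e-9 & times_ms < window_ms[2] - 1e-9)
}

#' Per-participant average hit and error curves
#'
#' Averages the retained clear-hit and clear-error epochs of one channel,
#' re-aligned to the per-epoch markers: a release-locked curve (for the
#' Ne/ERN analysis) and a feedback-locked curve (for the FRN analysis).
#'
#' @param epochs an `sk_epochs` (baseline-corrected).
#' @param channel channel label, default `"FCz"`.
#' @param release_span_ms,feedback_span_ms time spans (ms, relative to the
#'   marker) of the two output grids. Both must be covered by every retained
#'   epoch.
#' @return list with elements `hit` and `error`, each a list of `release`
#'   and `feedback` curves (`times_ms`, `amplitude`) plus `n`; and the
#'   per-class epoch counts.
#' @export
outcome_averages <- function(epochs, channel = "FCz",
                             release_span_ms = c(-600, 1348),
                             feedback_span_ms = c(-600, 498)) {
  info <- epochs$info
  use <- !info$rejected & info$erp_class %in% c("clear_hit", "clear_error")
  if (!any(use & info$erp_class == "clear_hit") ||
      !any(use & info$erp_class == "clear_error"))
    stop("participant lacks retained clear_hit or clear_error epochs",
         call. = FALSE)
  chan <- match(channel, epochs$channels)
  if (is.na(chan)) stop("channel not found: ", channel, call. = FALSE)
  fs <- epochs$fs
  locked <- function(e, offset, span) {
    k0 <- round(span[1] / 1000 * fs); k1 <- round(span[2] / 1000 * fs)
    i0 <- match(TRUE, abs(epochs$times_ms - (offset + k0) * 1000 / fs) < 1e-6)
    if (is.na(i0) || i0 + (k1 - k0) > length(epochs$times_ms))
      stop("window error: locked span exceeds epoch", call. = FALSE)
    epochs$data[e, i0:(i0 + (k1 - k0)), chan]
  }
  avg_class <- function(cls) {
    eps <- which(use & info$erp_class == cls)
    rel <- rowMeans(vapply(eps, function(e)
      locked(e, info$release_offset[e], release_span_ms),
      numeric(diff(round(release_span_ms / 1000 * fs)) + 1)))
    fb <- rowMeans(vapply(eps, function(e)
      locked(e, info$feedback_offset[e], feedback_span_ms),
      numeric(diff(round(feedback_span_ms / 1000 * fs)) + 1)))
    rel_t <- seq(round(release_span_ms[1] / 1000 * fs),
                 round(release_span_ms[2] / 1000 * fs)) * 1000 / fs
    fb_t <- seq(round(feedback_span_ms[1] / 1000 * fs),
                round(feedback_span_ms[2] / 1000 * fs)) * 1000 / fs
    list(release = list(times_ms = rel_t, amplitude = rel),
         feedback = list(times_ms = fb_t, amplitude = fb),
         n = length(eps))
  }
  list(hit = avg_class("clear_hit"), error = avg_class("clear_error"))
}

#' Error-minus-hit difference wave
#'
#' Pointwise subtraction of the average hit curve from the average error
#' curve, separately for the release-locked and feedback-locked variants.
#'
#' @param error_curve,hit_curve elements `error`/`hit` of
#'   [outcome_averages()] output (each with `release` and `feedback`
#'   curves).
#' @param participant_id label stored in the result.
#' @return An object of class `sk_diffwave`.
#' @export
difference_wave <- function(error_curve, hit_curve, participant_id = NA) {
  stopifnot(isTRUE(all.equal(error_curve$release$times_ms,
                             hit_curve$release$times_ms)),
            isTRUE(all.equal(error_curve$feedback$times_ms,
                             hit_curve$feedback$times_ms)))
  structure(list(
    release = list(times_ms = error_curve$release$times_ms,
                   amplitude = error_curve$release$amplitude -
                     hit_curve$release$amplitude),
    feedback = list(times_ms = error_curve$feedback$times_ms,
                    amplitude = error_curve$feedback$amplitude -
                      hit_curve$feedback$amplitude),
    n_error = error_curve$n, n_hit = hit_curve$n,
    participant_id = participant_id), class = "sk_diffwave")
}

#' Window amplitudes of a difference wave
#'
#' Mean and peak amplitude over the effect windows. The mean is the
#' arithmetic mean over the half-open `[start, end)` sample set; the peak is
#' the window minimum (the potentials under study are negative deflections).
#' The Ne/ERN window is taken on the release-locked variant, the FRN window
#' on the feedback-locked variant.
#'
#' @param wave an `sk_diffwave`.
#' @param windows an [analysis_windows()].
#' @return data.frame with one row per window: `window`, `mean_uV`,
#'   `peak_uV`, `n_error`, `n_hit`.
#' @export
window_stats <- function(wave, windows = analysis_windows()) {
  one <- function(curve, win, label) {
    sel <- window_sample_index(curve$times_ms, win)
    step <- curve$times_ms[2] - curve$times_ms[1]
    if (!length(sel) ||
        win[1] < curve$times_ms[1] - 1e-9 ||
        win[2] > curve$times_ms[length(curve$times_ms)] + step)
      stop("window error: ", label, " outside wave span", call. = FALSE)
    data.frame(window = label, mean_uV = mean(curve$amplitude[sel]),
               peak_uV = min(curve$amplitude[sel]),
               n_error = wave$n_error, n_hit = wave$n_hit)
  }
  rbind(one(wave$release, windows$effw_ern, "effw_ern"),
        one(wave$feedback, windows$effw_frn, "effw_frn"))
}

#' Grand-average difference wave
#'
#' Pointwise mean of per-participant difference waves sharing a time base.
#'
#' @param waves list of `sk_diffwave` objects.
#' @return An `sk_diffwave` with `participant_id = "grand"`.
#' @export
grand_average <- function(waves) {
  stopifnot(length(waves) >= 1)
  ref <- waves[[1]]
  for (w in waves)
    stopifnot(isTRUE(all.equal(w$release$times_ms, ref$release$times_ms)),
              isTRUE(all.equal(w$feedback$times_ms, ref$feedback$times_ms)))
  rel <- rowMeans(vapply(waves, function(w) w$release$amplitude,
                         numeric(length(ref$release$amplitude))))
  fb <- rowMeans(vapply(waves, function(w) w$feedback$amplitude,
                        numeric(length(ref$feedback$amplitude))))
  structure(list(
    release = list(times_ms = ref$release$times_ms, amplitude = rel),
    feedback = list(times_ms = ref$feedback$times_ms, amplitude = fb),
    n_error = sum(vapply(waves, `[[`, 0, "n_error")),
    n_hit = sum(vapply(waves, `[[`, 0, "n_hit")),
    participant_id = "grand"), class = "sk_diffwave")
}

#' @export
print.sk_diffwave <- function(x, ...) {
  cat(sprintf(paste0("<sk_diffwave> participant %s: release-locked",
                     " [%g, %g] ms, feedback-locked [%g, %g] ms",
                     " (%d error / %d hit epochs)\n"),
              as.character(x$participant_id),
              min(x$release$times_ms), max(x$release$times_ms),
              min(x$feedback$times_ms), max(x$feedback$times_ms),
              x$n_error, x$n_hit))
  invisible(x)
}

#' Plot a difference wave
#'
#' Base-graphics display of the release-locked and feedback-locked
#' difference curves with the effect windows shaded.
#'
#' @param x an `sk_diffwave`.
#' @param windows an [analysis_windows()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sk_diffwave <- function(x, windows = analysis_windows(), ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  shade <- function(win) graphics::rect(win[1], -1e6, win[2], 1e6,
                                        col = "grey90", border = NA)
  graphics::plot(x$release$times_ms, x$release$amplitude, type = "n",
                 xlab = "time after release (ms)",
                 ylab = "error - hit (microvolts)",
                 main = "release-locked", ...)
  shade(windows$effw_ern)
  graphics::lines(x$release$times_ms, x$release$amplitude)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::plot(x$feedback$times_ms, x$feedback$amplitude, type = "n",
                 xlab = "time after feedback (ms)",
                 ylab = "error - hit (microvolts)",
                 main = "feedback-locked", ...)
  shade(windows$effw_frn)
  graphics::lines(x$feedback$times_ms, x$feedback$amplitude)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
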