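#' Cohort design for synthetic EEG generation
#'
#' Bundles everything the generator needs for one experimental condition.
#' Defaults mirror the study conditions of the task: the observation
#' (`"Visual"`) condition has 18 participants and 280 replayed trials
#' composed of 50 percent hits and 50 percent misses, with design-point
#' component amplitudes Ne/ERN -0.6 and FRN -3.4 microvolts; the active
#' no-vision (`"EffProp"`) condition has 17 participants and 430 executed
#' trials with natural outcome rates and design points Ne/ERN 0.05 and FRN
#' -5.6 microvolts. Sampling rate is 500 Hz.
#'
#' @param condition `"Visual"` or `"EffProp"`.
#' @param n_participants cohort size (>= 2 for group inference).
#' @param trials_per_participant trials per session.
#' @param error_fraction fraction of misses; `NULL` for natural rates.
#' @param components named list of [erp_component()] specs.
#' @param between_participant_amplitude_sd numeric (recycled over
#'   components): SD of per-participant true peak amplitudes around the
#'   design points (microvolts).
#' @param sampling_rate Hz.
#' @param noise list with `pink_sd`, `white_sd`, `alpha`, `f_floor`; see
#'   [generate_noise()].
#' @param channels channel labels; must include `"FCz"`. Mastoids `"M1"`,
#'   `"M2"` are appended automatically if absent.
#' @param topography named attenuation weights by which components project
#'   to each channel (FCz carries weight 1).
#' @param skill_sd SD (log scale) of the per-participant multiplier on the
#'   release scatter; produces between-participant hit-rate spread of the
#'   order seen in trained cohorts (roughly 10-15 percentage points).
#' @param sim_args list of overrides passed to [simulate_trials()].
#' @return An object of class `sk_design`.
#' @examples
#' cohort_design("Visual", n_participants = 4, trials_per_participant = 24)
#' @export
cohort_design <- function(condition = c("Visual", "EffProp"),
                          n_participants = NULL,
                          trials_per_participant = NULL,
                          error_fraction = NULL,
                          components = NULL,
                          between_participant_amplitude_sd = c(1.6, 4.0),
                          sampling_rate = 500,
                          noise = list(pink_sd = 8, white_sd = 3, alpha = 1,
                                       f_floor = 0.25),
                          channels = c("Fz", "FCz", "Cz"),
                          topography = c(FCz = 1, Fz = 0.6, Cz = 0.6,
                                         F3 = 0.4, F4 = 0.4, C3 = 0.4,
                                         C4 = 0.4, P3 = 0.2, Pz = 0.3,
                                         P4 = 0.2, M1 = 0, M2 = 0),
                          skill_sd = 0.35,
                          sim_args = list()) {
  condition <- match.arg(condition)
  if (is.null(n_participants))
    n_participants <- if (condition == "Visual") 18L else 17L
  if (is.null(trials_per_participant))
    trials_per_participant <- if (condition == "Visual") 280L else 430L
  if (condition == "Visual" && is.null(error_fraction)) error_fraction <- 0.5
  if (is.null(components)) {
    components <- if (condition == "Visual") {
      list(ern = erp_component("release", c(200, 350), -0.6),
           frn = erp_component("feedback", c(150, 350), -3.4))
    } else {
      list(ern = erp_component("release", c(200, 350), 0.05),
           frn = erp_component("feedback", c(150, 350), -5.6))
    }
  }
  if (!is.null(error_fraction) &&
      (error_fraction <= 0 || error_fraction >= 1))
    stop("error_fraction must lie in (0, 1)", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  sd_vec <- rep_len(between_participant_amplitude_sd, length(components))
  names(sd_vec) <- names(components)
  channels <- union(channels, c("FCz", "M1", "M2"))
  structure(list(condition = condition, n_participants = n_participants,
                 trials_per_participant = trials_per_participant,
                 error_fraction = error_fraction, components = components,
                 between_participant_amplitude_sd = sd_vec,
                 sampling_rate = sampling_rate, noise = noise,
                 channels = channels, topography = topography,
                 skill_sd = skill_sd, sim_args = sim_args),
            class = "sk_design")
}

#' Generate a continuous synthetic EEG recording for one participant
#'
#' Lays 1/f-plus-white Gaussian background noise over all channels, embeds
#' event markers (trial start, ball release, outcome feedback, and outcome
#' class) for every trial, and adds the design's ERP components, scaled by
#' the participant's true amplitudes and the channel topography, time-locked
#' to the release/feedback markers of the trials they apply to. The feedback
#' marker is placed exactly `round(0.850 * sampling_rate)` samples after the
#' release marker of the same trial.
#'
#' @param trials trial table from [simulate_trials()].
#' @param design an [cohort_design()] object.
#' @param amplitudes named numeric vector of true peak amplitudes
#'   (microvolts), one per design component; defaults to the design points.
#' @param participant_id stored in the recording.
#' @return An object of class `sk_recording`: list with `samples`
#'   (n x channels matrix, microvolts), `channels`, `fs`, `markers`
#'   (data.frame `type`, `trial_id`, `sample`), `participant_id`,
#'   `condition`.
#' @export
generate_recording <- function(trials, design,
                               amplitudes = NULL,
                               participant_id = 1L) {
  fs <- design$sampling_rate
  if (is.null(amplitudes))
    amplitudes <- vapply(design$components, `[[`, 0, "peak_amplitude")
  chans <- design$channels
  k <- length(chans)
  n <- ceiling((max(trials$t_feedback_s) + 1.5) * fs)
  if (min(trials$t_start_s) < 0.7)
    stop("marker-placement error: first trial too close to recording start",
         call. = FALSE)
  samples <- generate_noise_matrix(n, k, fs = fs,
                                   pink_sd = design$noise$pink_sd,
                                   white_sd = design$noise$white_sd,
                                   alpha = design$noise$alpha,
                                   f_floor = design$noise$f_floor)
  colnames(samples) <- chans
  delay_smp <- round(0.850 * fs)
  rel_smp <- round(trials$t_release_s * fs) + 1L
  start_smp <- round(trials$t_start_s * fs) + 1L
  fb_smp <- rel_smp + delay_smp
  if (any(fb_smp > n) || any(start_smp < 1L))
    stop("marker-placement error: trial events outside recording span",
         call. = FALSE)
  topo <- design$topography[chans]
  topo[is.na(topo)] <- 0
  for (j in seq_along(design$components)) {
    comp <- design$components[[j]]
    amp <- amplitudes[[names(design$components)[j]]]
    lock <- if (comp$lock_event == "release") rel_smp else fb_smp
    rows <- if (comp$applies_to == "all_trials") seq_len(nrow(trials)) else
      which(trials$outcome == "miss")
    k0 <- ceiling(comp$window[1] / 1000 * fs)
    k1 <- floor(comp$window[2] / 1000 * fs)
    wav <- component_unit_waveform(comp, (k0:k1) / fs * 1000) * amp
    for (i in rows) {
      idx <- (lock[i] + k0):(lock[i] + k1)
      samples[idx, ] <- samples[idx, ] + wav %o% unname(topo)
    }
  }
  markers <- rbind(
    data.frame(type = "S_trialstart", trial_id = trials$trial_id,
               sample = start_smp),
    data.frame(type = "S_release", trial_id = trials$trial_id,
               sample = rel_smp),
    data.frame(type = "S_feedback", trial_id = trials$trial_id,
               sample = fb_smp),
    data.frame(type = ifelse(trials$outcome == "hit", "S_hit", "S_error"),
               trial_id = trials$trial_id, sample = fb_smp))
  markers <- markers[order(markers$sample, markers$trial_id), ]
  rownames(markers) <- NULL
  structure(list(samples = samples, channels = chans, fs = fs,
                 markers = markers, participant_id = participant_id,
                 condition = design$condition),
            class = "sk_recording")
}

#' Generate a synthetic cohort
#'
#' Derives one independent substream seed per participant from the master
#' seed (by drawing `n` integers from the seeded generator), draws each
#' participant's true component amplitudes around the design points, then
#' simulates that participant's trial session and continuous recording.
#'
#' @param design an [cohort_design()] object.
#' @param seed master seed (integer).
#' @param out_dir optional directory; when given, each participant's
#'   recording is written as a BrainVision triplet plus trial-table TSV and
#'   only file paths are kept in memory.
#' @return list of participants, each a list with `id`, `seed`,
#'   `amplitudes`, `trials`, and `recording` (or `files` when `out_dir` is
#'   used).
#' @export
generate_cohort <- function(design, seed = 1L, out_dir = NULL) {
  if (design$n_participants < 2)
    stop("need n_participants >= 2 for group inference", call. = FALSE)
  set.seed(seed)
  p_seeds <- sample.int(.Machine$integer.max, design$n_participants)
  lapply(seq_len(design$n_participants), function(i) {
    set.seed(p_seeds[i])
    amps <- vapply(seq_along(design$components), function(j)
      rnorm(1, design$components[[j]]$peak_amplitude,
            design$between_participant_amplitude_sd[j]), 0)
    names(amps) <- names(design$components)
    skill <- exp(rnorm(1, 0, design$skill_sd))
    sim <- c(list(n_trials = design$trials_per_participant,
                  condition = design$condition,
                  error_fraction = design$error_fraction),
             design$sim_args)
    sim$sd_angle_deg <- (sim$sd_angle_deg %||% 8) * skill
    sim$sd_velocity_deg_s <- (sim$sd_velocity_deg_s %||% 40) * skill
    trials <- do.call(simulate_trials, sim)
    rec <- generate_recording(trials, design, amplitudes = amps,
                              participant_id = i)
    out <- list(id = i, seed = p_seeds[i], amplitudes = amps, trials = trials)
    if (is.null(out_dir)) {
      out$recording <- rec
    } else {
      base <- file.path(out_dir, sprintf("%s_p%02d", design$condition, i))
      write_brainvision(rec, base)
      write_trial_table(trials, paste0(base, "_trials.tsv"))
      out$files <- list(vhdr = paste0(base, ".vhdr"),
                        trials = paste0(base, "_trials.tsv"))
    }
    out
  })
}

#' Directly simulate an event-locked epoch set
#'
#' Fast path for simulation studies: generates release-anchored epochs
#' (background noise plus injected components on error trials) without
#' assembling a continuous recording, using the same component and noise
#' primitives as [generate_recording()]. Single channel (FCz), release
#' offset 0, feedback offset exactly 0.850 s.
#'
#' @param n_error,n_hit number of clear-error / clear-hit epochs.
#' @param components named list of [erp_component()] specs (applied to the
#'   error epochs).
#' @param amplitudes named peak amplitudes (microvolts); defaults to the
#'   component design points.
#' @param noise list as in [cohort_design()].
#' @param fs sampling rate (Hz).
#' @param epoch_window_ms epoch span relative to release (ms).
#' @return An `sk_epochs` object (see [segment_epochs()]).
#' @export
simulate_epoch_set <- function(n_error, n_hit, components,
                               amplitudes = NULL,
                               noise = list(pink_sd = 8, white_sd = 3,
                                            alpha = 1, f_floor = 0.25),
                               fs = 500,
                               epoch_window_ms = c(-600, 2200)) {
  if (is.null(amplitudes))
    amplitudes <- vapply(components, `[[`, 0, "peak_amplitude")
  k0 <- round(epoch_window_ms[1] / 1000 * fs)
  k1 <- round(epoch_window_ms[2] / 1000 * fs)
  times_ms <- (k0:k1) / fs * 1000
  nt <- length(times_ms)
  n_ep <- n_error + n_hit
  noise_mat <- generate_noise_matrix(nt, n_ep, fs = fs,
                                     pink_sd = noise$pink_sd,
                                     white_sd = noise$white_sd,
                                     alpha = noise$alpha,
                                     f_floor = noise$f_floor)
  delay_ms <- round(0.850 * fs) / fs * 1000
  sig <- numeric(nt)
  for (j in seq_along(components)) {
    comp <- components[[j]]
    amp <- amplitudes[[names(components)[j]]]
    shift <- if (comp$lock_event == "feedback") delay_ms else 0
    sig <- sig + component_unit_waveform(comp, times_ms - shift) * amp
  }
  data <- array(0, dim = c(n_ep, nt, 1L),
                dimnames = list(NULL, NULL, "FCz"))
  for (e in seq_len(n_ep)) data[e, , 1] <- noise_mat[, e]
  if (n_error > 0)
    for (e in seq_len(n_error)) data[e, , 1] <- data[e, , 1] + sig
  info <- data.frame(
    trial_id = seq_len(n_ep),
    outcome = rep(c("miss", "hit"), c(n_error, n_hit)),
    erp_class = rep(c("clear_error", "clear_hit"), c(n_error, n_hit)),
    release_offset = 0L,
    feedback_offset = as.integer(round(0.850 * fs)),
    rejected = FALSE)
  structure(list(data = data, times_ms = times_ms, channels = "FCz",
                 fs = fs, info = info, anchor = "release",
                 participant_id = NA_integer_, condition = NA_character_,
                 n_dropped_edge = 0L),
            class = "sk_epochs")
}
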