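#' Default pipeline configuration
#'
#' One nested list holding every constant of the task and analysis: geometry
#' (post 0.25 m at the origin, target 0.05 m at (0.35, 1.0), ball 0.05 m),
#' lever (0.4 m, pivot (0, -1.5)), flight dynamics, classification
#' thresholds (hit 0.10 m, clear hit 0.07 m, clear error 0.12 m, onset
#' 50 degrees/s), 0.2-30 Hz Butterworth filtering, 500 Hz sampling, analysis
#' windows (baseline 0-200, Ne/ERN 200-350 ms post release, FRN 150-350 ms
#' post feedback), the 850 ms feedback delay, condition designs, noise and
#' between-participant variability of the generator, and statistics options.
#' The list is plain (YAML-serializable) and round-trips losslessly through
#' [save_config()] / [load_config()].
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    geometry = list(post_center = c(0, 0), post_radius = 0.25,
                    target_center = c(0.35, 1.0), target_radius = 0.05,
                    ball_radius = 0.05),
    lever = list(pivot = c(0, -1.5), length = 0.4),
    oscillator = list(omega = 3.0, tau = 10, flight_duration = 2,
                      dt = 0.002),
    thresholds = list(hit = 0.10, clear_hit = 0.07, clear_error = 0.12,
                      onset_velocity = 50),
    feedback_delay_s = 0.850,
    sampling_rate = 500,
    filter = list(low = 0.2, high = 30, order = 2, enabled = TRUE),
    reference = "linked_mastoids",
    artifact_threshold = 100,
    windows = list(baseline = c(0, 200), effw_ern = c(200, 350),
                   effw_frn = c(150, 350)),
    sim = list(aim_angle_deg = 80, aim_velocity_deg_s = 300,
               sd_angle_deg = 8, sd_velocity_deg_s = 40, skill_sd = 0.35,
               release_latency_s = c(0.8, 1.4), inter_trial_gap_s = 1.6),
    noise = list(pink_sd = 8, white_sd = 3, alpha = 1, f_floor = 0.25),
    between_participant_amplitude_sd = c(1.6, 4.0),
    channels = c("Fz", "FCz", "Cz"),
    conditions = list(
      Visual = list(n_participants = 18, trials_per_participant = 280,
                    error_fraction = 0.5,
                    segment = list(anchor_event = "S_trialstart",
                                   start_offset_ms = -600,
                                   end_offset_ms = 2800),
                    components = list(
                      ern = list(lock_event = "release",
                                 window = c(200, 350),
                                 peak_amplitude = -0.6,
                                 shape = "half_cosine",
                                 applies_to = "error_trials"),
                      frn = list(lock_event = "feedback",
                                 window = c(150, 350),
                                 peak_amplitude = -3.4,
                                 shape = "half_cosine",
                                 applies_to = "error_trials"))),
      EffProp = list(n_participants = 17, trials_per_participant = 430,
                     error_fraction = NULL,
                     segment = list(anchor_event = "S_release",
                                    start_offset_ms = -600,
                                    end_offset_ms = 2200),
                     components = list(
                       ern = list(lock_event = "release",
                                  window = c(200, 350),
                                  peak_amplitude = 0.05,
                                  shape = "half_cosine",
                                  applies_to = "error_trials"),
                       frn = list(lock_event = "feedback",
                                  window = c(150, 350),
                                  peak_amplitude = -5.6,
                                  shape = "half_cosine",
                                  applies_to = "error_trials")))),
    practice = list(n_sessions = 4, trials_per_session = 400,
                    n_participants = 19,
                    jitter_multipliers = c(1.38, 1.12, 0.95, 0.80)),
    stats = list(tail = "negative", bf_scale = 0.707,
                 contrast_variant = "pooled",
                 contrast_tail = list(effw_ern = "negative",
                                      effw_frn = "positive"))
  )
}

#' Load (and validate) a pipeline configuration
#'
#' Reads a YAML file, checks every key against the default configuration
#' schema (unknown keys are rejected by name), and fills unspecified values
#' with defaults. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(default_config())
  merge_config(default_config(), user, "config")
}

merge_config <- function(defaults, user, where) {
  if (!is.list(user)) stop("config error: ", where, " must be a mapping",
                           call. = FALSE)
  if (is.null(names(user)) && length(user))
    stop("config error: ", where, " must have named keys", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config error: unknown key '", where, "$", unknown[1], "'",
         call. = FALSE)
  for (key in names(user)) {
    # conditions$*$error_fraction may legitimately be NULL in the defaults
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(where, "$", key))
    } else {
      # single-bracket assignment keeps explicit NULLs (e.g. a condition
      # without a fixed error fraction) instead of dropping the key
      defaults[key] <- list(simplify_scalar(user[[key]]))
    }
  }
  defaults
}

# yaml reads sequences as lists; flatten plain numeric/character sequences
simplify_scalar <- function(x) {
  if (is.list(x) && length(x) && is.null(names(x)) &&
      all(vapply(x, function(e) is.atomic(e) && length(e) == 1, TRUE)))
    return(unlist(x))
  x
}

#' @rdname load_config
#' @param config configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical YAML serialization; changes if and only if
#' some configuration value changes. Recorded in the run manifest.
#'
#' @param config configuration list.
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}
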