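# helpers translating the plain config into the package's objects

config_geometry <- function(cfg)
  task_geometry(cfg$geometry$post_center, cfg$geometry$post_radius,
                cfg$geometry$target_center, cfg$geometry$target_radius,
                cfg$geometry$ball_radius)

config_lever <- function(cfg) lever_config(cfg$lever$pivot, cfg$lever$length)

config_oscillator <- function(cfg)
  oscillator_params(cfg$oscillator$omega, cfg$oscillator$tau,
                    cfg$oscillator$flight_duration, cfg$oscillator$dt)

config_components <- function(cond_cfg)
  lapply(cond_cfg$components, function(c)
    erp_component(c$lock_event, c$window, c$peak_amplitude, c$shape,
                  c$applies_to))

#' Build a cohort design from a configuration
#'
#' Translates one condition block of the plain configuration list into the
#' [cohort_design()] object the generator consumes.
#'
#' @param cfg configuration list ([default_config()]).
#' @param condition `"Visual"` or `"EffProp"`.
#' @return An `sk_design`.
#' @export
config_design <- function(cfg, condition) {
  cond <- cfg$conditions[[condition]]
  cohort_design(
    condition = condition,
    n_participants = cond$n_participants,
    trials_per_participant = cond$trials_per_participant,
    error_fraction = cond$error_fraction,
    components = config_components(cond),
    between_participant_amplitude_sd = cfg$between_participant_amplitude_sd,
    sampling_rate = cfg$sampling_rate,
    noise = cfg$noise,
    channels = cfg$channels,
    skill_sd = cfg$sim$skill_sd,
    sim_args = list(aim_angle_deg = cfg$sim$aim_angle_deg,
                    aim_velocity_deg_s = cfg$sim$aim_velocity_deg_s,
                    sd_angle_deg = cfg$sim$sd_angle_deg,
                    sd_velocity_deg_s = cfg$sim$sd_velocity_deg_s,
                    release_latency_s = cfg$sim$release_latency_s,
                    inter_trial_gap_s = cfg$sim$inter_trial_gap_s,
                    geometry = config_geometry(cfg),
                    lever = config_lever(cfg),
                    params = config_oscillator(cfg),
                    thresholds = cfg$thresholds[c("hit", "clear_hit",
                                                  "clear_error")]))
}

config_segment_spec <- function(cfg, condition) {
  seg <- cfg$conditions[[condition]]$segment
  segment_spec(condition, anchor_event = seg$anchor_event,
               start_offset_ms = seg$start_offset_ms,
               end_offset_ms = seg$end_offset_ms)
}

#' Process one participant's recording into window amplitudes
#'
#' The per-participant analysis chain: band-pass filter and re-reference,
#' cut condition-specific epochs, reject artifact epochs, baseline-correct,
#' average clear hits and clear errors (marker-aligned), form the
#' error-minus-hit difference wave, and measure window amplitudes.
#'
#' @param recording an `sk_recording`.
#' @param trials the matching trial table.
#' @param cfg configuration list ([default_config()]).
#' @param condition `"Visual"` or `"EffProp"`.
#' @return list with `wave` (`sk_diffwave`), `stats` (window amplitude
#'   rows), and attrition counts.
#' @export
process_participant <- function(recording, trials, cfg, condition) {
  filt <- if (isTRUE(cfg$filter$enabled))
    list(low = cfg$filter$low, high = cfg$filter$high,
         order = cfg$filter$order) else NULL
  rec <- preprocess(recording, filter = filt, reference = cfg$reference)
  ep <- segment_epochs(rec, trials, config_segment_spec(cfg, condition))
  ep <- reject_artifacts(ep, cfg$artifact_threshold)
  win <- analysis_windows(cfg$windows$baseline, cfg$windows$effw_ern,
                          cfg$windows$effw_frn)
  ep <- baseline_correct(ep, win)
  av <- outcome_averages(ep)
  wave <- difference_wave(av$error, av$hit,
                          participant_id = recording$participant_id)
  list(wave = wave, stats = window_stats(wave, win),
       n_dropped_edge = ep$n_dropped_edge,
       n_rejected = sum(ep$info$rejected))
}

#' Simulate practice-phase hit rates
#'
#' Hit rate per participant and practice session under the generator's
#' release-scatter model; scatter shrinks across sessions by the configured
#' multipliers, emulating improvement with practice.
#'
#' @param cfg configuration list.
#' @param n_participants cohort size.
#' @param trials_per_session throws per session.
#' @return data.frame with `participant`, `session`, `hit_rate_pct`.
#' @export
simulate_practice_hit_rates <- function(cfg = default_config(),
                                        n_participants =
                                          cfg$practice$n_participants,
                                        trials_per_session =
                                          cfg$practice$trials_per_session) {
  mult <- cfg$practice$jitter_multipliers
  rows <- list()
  for (p in seq_len(n_participants)) {
    skill <- exp(rnorm(1, 0, cfg$sim$skill_sd))
    for (s in seq_len(cfg$practice$n_sessions)) {
      tr <- simulate_trials(
        trials_per_session, condition = "practice", session = s,
        aim_angle_deg = cfg$sim$aim_angle_deg,
        aim_velocity_deg_s = cfg$sim$aim_velocity_deg_s,
        sd_angle_deg = cfg$sim$sd_angle_deg * mult[s] * skill,
        sd_velocity_deg_s = cfg$sim$sd_velocity_deg_s * mult[s] * skill,
        geometry = config_geometry(cfg), lever = config_lever(cfg),
        params = config_oscillator(cfg))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, session = s, hit_rate_pct = hit_rate(tr))
    }
  }
  do.call(rbind, rows)
}

#' Run the full simulate - synthesize - analyze pipeline
#'
#' End-to-end driver: simulates practice hit rates and their by-session
#' analysis of variance, then for each experimental condition generates a
#' synthetic cohort (trials plus continuous EEG), runs every participant
#' through the ERP chain ([process_participant()]), computes group-level
#' inference on the window mean amplitudes (directional one-sample t, 95
#' percent CI, Cohen's d, JZS Bayes factor with evidence label), the
#' between-condition contrasts, and grand-average difference waves.
#' Fully reproducible from `(config, seed)`.
#'
#' @param cfg configuration list ([default_config()] or [load_config()]).
#' @param seed master seed.
#' @param out_dir optional output directory for TSV/JSON result files.
#' @return An object of class `sk_results`: list with `amplitudes` (per
#'   participant x window), `group` (inference table), `contrasts`,
#'   `hit_rates`, `practice`, `practice_anova`, `grand_waves`, `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(), seed = 1L, out_dir = NULL) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(cfg$conditions) + 1L)
  set.seed(seeds[length(seeds)])
  practice <- simulate_practice_hit_rates(cfg)
  practice_anova <- one_way_anova(practice$hit_rate_pct, practice$session)

  amp_rows <- list(); hit_rows <- list(); grand_waves <- list()
  attrition <- list()
  for (ci in seq_along(cfg$conditions)) {
    condition <- names(cfg$conditions)[ci]
    design <- config_design(cfg, condition)
    cohort <- generate_cohort(design, seed = seeds[ci])
    waves <- list()
    for (p in cohort) {
      # a participant without retained clear hits AND clear errors cannot
      # contribute a difference wave; exclude from group stats, logged
      res <- tryCatch(process_participant(p$recording, p$trials, cfg,
                                          condition),
                      error = function(e) {
                        if (!grepl("lacks retained", conditionMessage(e)))
                          stop(e)
                        NULL
                      })
      if (is.null(res)) {
        message("participant ", p$id, " (", condition,
                ") excluded: no retained clear-hit/clear-error epochs")
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          participant = p$id, condition = condition,
          hit_rate_pct = hit_rate(p$trials))
        next
      }
      waves[[length(waves) + 1L]] <- res$wave
      st <- res$stats
      st$participant <- p$id; st$condition <- condition
      amp_rows[[length(amp_rows) + 1L]] <- st
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        participant = p$id, condition = condition,
        hit_rate_pct = hit_rate(p$trials))
      attrition[[length(attrition) + 1L]] <- data.frame(
        participant = p$id, condition = condition,
        n_trials = nrow(p$trials),
        n_excluded_class = sum(p$trials$erp_class == "excluded"),
        n_dropped_edge = res$n_dropped_edge, n_rejected = res$n_rejected)
    }
    grand_waves[[condition]] <- grand_average(waves)
  }
  amplitudes <- do.call(rbind, amp_rows)
  hit_rates <- do.call(rbind, hit_rows)

  group_rows <- list()
  for (condition in names(cfg$conditions)) {
    for (w in unique(amplitudes$window)) {
      vals <- amplitudes$mean_uV[amplitudes$condition == condition &
                                   amplitudes$window == w]
      peaks <- amplitudes$peak_uV[amplitudes$condition == condition &
                                    amplitudes$window == w]
      inf <- window_inference(vals, tail = cfg$stats$tail,
                              scale = cfg$stats$bf_scale)
      group_rows[[length(group_rows) + 1L]] <- data.frame(
        condition = condition, window = w, n = inf$n,
        mean_uV = inf$estimate, peak_uV = mean(peaks),
        ci_low = inf$ci95[1], ci_high = inf$ci95[2],
        t = inf$t, df = inf$df, p = inf$p, d = inf$cohens_d,
        bf10 = inf$bf10, label = inf$evidence_label)
    }
  }
  group <- do.call(rbind, group_rows)

  contrast_rows <- list()
  conds <- names(cfg$conditions)
  if (length(conds) == 2) {
    for (w in unique(amplitudes$window)) {
      g1 <- amplitudes$mean_uV[amplitudes$condition == conds[1] &
                                 amplitudes$window == w]
      g2 <- amplitudes$mean_uV[amplitudes$condition == conds[2] &
                                 amplitudes$window == w]
      tl <- cfg$stats$contrast_tail[[w]] %||% "two_sided"
      tt <- two_group_t(g1, g2, variant = cfg$stats$contrast_variant,
                        tail = tl)
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        window = w, mean_diff_uV = tt$estimate, t = tt$t, df = tt$df,
        p = tt$p, d = tt$cohens_d, tail = tl)
    }
  }
  contrasts <- if (length(contrast_rows)) do.call(rbind, contrast_rows)
    else NULL

  manifest <- list(package = "skittlesERP",
                   version = as.character(utils::packageVersion("skittlesERP")),
                   seed = seed, config_hash = config_hash(cfg))
  out <- structure(list(amplitudes = amplitudes, group = group,
                        contrasts = contrasts, hit_rates = hit_rates,
                        practice = practice,
                        practice_anova = practice_anova,
                        grand_waves = grand_waves,
                        attrition = do.call(rbind, attrition),
                        manifest = manifest),
                   class = "sk_results")
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' Write a results bundle to disk
#'
#' @param results an `sk_results` from [run_pipeline()].
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(results$amplitudes, "window_amplitudes.tsv")
  tsv(results$group, "group_stats.tsv")
  if (!is.null(results$contrasts)) tsv(results$contrasts, "contrasts.tsv")
  tsv(results$hit_rates, "hit_rates.tsv")
  for (cond in names(results$grand_waves)) {
    w <- results$grand_waves[[cond]]
    tsv(data.frame(time_ms = w$release$times_ms,
                   microvolts = w$release$amplitude),
        sprintf("grand_diffwave_%s_release.tsv", cond))
    tsv(data.frame(time_ms = w$feedback$times_ms,
                   microvolts = w$feedback$amplitude),
        sprintf("grand_diffwave_%s_feedback.tsv", cond))
  }
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sk_results <- function(x, ...) {
  cat("<sk_results>\n")
  cat(sprintf("  practice: F(%d,%d) = %.3f, p = %.4g\n",
              x$practice_anova$df1, x$practice_anova$df2,
              x$practice_anova$F, x$practice_anova$p))
  cat("  group inference (window mean amplitudes):\n")
  print(x$group, digits = 3, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("  condition contrasts:\n")
    print(x$contrasts, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
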