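#' Simulate a session of throwing trials
#'
#' Draws release parameters from a Gaussian scatter around a participant's
#' aim point, scores each throw through the ball-flight model, classifies
#' outcomes, and lays the trials out on a recording clock: the ball release
#' of trial k happens `release_latency` after trial start, outcome feedback
#' exactly 0.850 s after release, and the next trial starts after
#' `inter_trial_gap`. The default aim point and scatter yield hit rates in
#' the 50-80 percent range typical of trained participants.
#'
#' For the observation condition the trial set can be balanced: with
#' `error_fraction` set, trials are drawn from an oversampled pool so that
#' the requested fraction of misses is met exactly (within one trial),
#' mirroring replayed observation blocks composed of a fixed hit:miss ratio.
#'
#' @param n_trials number of trials.
#' @param condition condition label stored in the table.
#' @param session session number stored in the table.
#' @param aim_angle_deg,aim_velocity_deg_s participant aim point.
#' @param sd_angle_deg,sd_velocity_deg_s release scatter (SDs).
#' @param error_fraction optional fraction of misses in `(0, 1)`; when set,
#'   the trial set is selected to match it.
#' @param release_latency_s range (length-2) of trial-start-to-release
#'   latencies; drawn uniformly per trial.
#' @param inter_trial_gap_s gap between feedback and the next trial start.
#' @param feedback_delay_s outcome feedback delay after release (0.850 s).
#' @param t_first_start_s recording time of the first trial start.
#' @param lever,geometry,params task configuration objects.
#' @param thresholds classification thresholds, see [classify_trial()].
#' @return data.frame (one row per trial) with columns `trial_id`, `session`,
#'   `condition`, `release_angle_deg`, `release_velocity_deg_s`, `d_m`,
#'   `post_hit`, `outcome`, `erp_class`, `t_start_s`, `t_release_s`,
#'   `t_feedback_s`.
#' @examples
#' set.seed(1)
#' tr <- simulate_trials(20)
#' hit_rate(tr)
#' @export
simulate_trials <- function(n_trials, condition = "EffProp", session = 6L,
                            aim_angle_deg = 80, aim_velocity_deg_s = 300,
                            sd_angle_deg = 8, sd_velocity_deg_s = 40,
                            error_fraction = NULL,
                            release_latency_s = c(0.8, 1.4),
                            inter_trial_gap_s = 1.6,
                            feedback_delay_s = 0.850,
                            t_first_start_s = 1.0,
                            lever = lever_config(),
                            geometry = task_geometry(),
                            params = oscillator_params(),
                            thresholds = list(hit = 0.10, clear_hit = 0.07,
                                              clear_error = 0.12)) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  draw <- function(n) {
    ang <- rnorm(n, aim_angle_deg, sd_angle_deg) %% 360
    vel <- rnorm(n, aim_velocity_deg_s, sd_velocity_deg_s)
    sc <- score_releases(ang, vel, lever = lever, geometry = geometry,
                         params = params)
    cls <- classify_trials(sc$d_m, sc$post_hit, thresholds)
    sc$outcome <- cls$outcome
    sc$erp_class <- cls$erp_class
    sc
  }
  if (is.null(error_fraction)) {
    pool <- draw(n_trials)
  } else {
    if (error_fraction <= 0 || error_fraction >= 1)
      stop("error_fraction must lie in (0, 1)", call. = FALSE)
    n_miss <- round(n_trials * error_fraction)
    n_hit <- n_trials - n_miss
    hits <- list(); misses <- list(); tries <- 0L
    while ((sum(vapply(hits, nrow, 1L)) < n_hit ||
            sum(vapply(misses, nrow, 1L)) < n_miss) && tries < 50L) {
      batch <- draw(max(4L * n_trials, 64L))
      batch <- batch[!batch$post_hit, ]  # replayed trials avoid post hits
      hits[[length(hits) + 1L]] <- batch[batch$outcome == "hit", ]
      misses[[length(misses) + 1L]] <- batch[batch$outcome == "miss", ]
      tries <- tries + 1L
    }
    hits <- do.call(rbind, hits); misses <- do.call(rbind, misses)
    if (nrow(hits) < n_hit || nrow(misses) < n_miss)
      stop("could not assemble the requested hit:miss composition; ",
           "check aim/scatter settings", call. = FALSE)
    pool <- rbind(hits[seq_len(n_hit), ], misses[seq_len(n_miss), ])
    pool <- pool[sample.int(nrow(pool)), ]
  }
  lat <- runif(n_trials, release_latency_s[1], release_latency_s[2])
  t_start <- numeric(n_trials)
  t_start[1] <- t_first_start_s
  if (n_trials > 1) {
    for (k in 2:n_trials)
      t_start[k] <- t_start[k - 1] + lat[k - 1] + feedback_delay_s +
        inter_trial_gap_s
  }
  t_release <- t_start + lat
  data.frame(trial_id = seq_len(n_trials), session = session,
             condition = condition,
             release_angle_deg = pool$angle_deg,
             release_velocity_deg_s = pool$velocity_deg_s,
             d_m = pool$d_m, post_hit = pool$post_hit,
             outcome = pool$outcome, erp_class = pool$erp_class,
             t_start_s = t_start, t_release_s = t_release,
             t_feedback_s = t_release + feedback_delay_s,
             row.names = NULL)
}

#' Write / read a trial table as TSV
#'
#' Plain tab-separated text with a header row; the standard interchange
#' format for trial records in this package.
#'
#' @param trials trial data.frame as returned by [simulate_trials()].
#' @param path file path.
#' @return `read_trial_table()` returns the trial data.frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("trial_id", "condition", "d_m", "post_hit", "outcome",
                "erp_class", "t_release_s", "t_feedback_s")
  missing <- setdiff(required, names(tr))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tr$post_hit <- as.logical(tr$post_hit)
  tr
}
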