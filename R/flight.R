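#' Simulate ball flight after release
#'
#' Closed-form flight of the damped two-dimensional harmonic oscillator about
#' the post center. Each axis follows
#' `x(t) = A * sin(omega * t + phi) * exp(-t / tau)`, with `A` and `phi`
#' solved from the release position and velocity:
#' `A * sin(phi) = p0` and `A * (omega * cos(phi) - sin(phi) / tau) = v0`.
#' Positions are expressed relative to the post center and sampled every
#' `dt` seconds over `flight_duration`.
#'
#' @param release an [release_state()] object.
#' @param params an [oscillator_params()] object.
#' @param geometry a [task_geometry()] object (supplies the post center the
#'   restoring force acts about).
#' @return An object of class `sk_trajectory`: list with `times` (s, starting
#'   at 0) and `positions` (n x 2 matrix, m).
#' @examples
#' traj <- simulate_flight(release_state(80, 300))
#' head(traj$positions)
#' @export
simulate_flight <- function(release, params = oscillator_params(),
                            geometry = task_geometry()) {
  p0 <- release$ball_position - geometry$post_center
  v0 <- release$ball_velocity
  if (all(p0 == 0) && all(v0 == 0))
    stop("degenerate trajectory: zero initial position and velocity",
         call. = FALSE)
  t <- seq(0, params$flight_duration, by = params$dt)
  decay <- if (is.finite(params$tau)) exp(-t / params$tau) else rep(1, length(t))
  pos <- vapply(1:2, function(i) {
    ab <- flight_coefficients(p0[i], v0[i], params$omega, params$tau)
    (ab[1] * sin(params$omega * t) + ab[2] * cos(params$omega * t)) * decay
  }, numeric(length(t)))
  pos <- sweep(pos, 2, geometry$post_center, "+")
  structure(list(times = t, positions = pos), class = "sk_trajectory")
}

# per-axis coefficients (a, b) of x(t) = (a sin wt + b cos wt) e^{-t/tau},
# i.e. b = A sin(phi), a = A cos(phi)
flight_coefficients <- function(p0, v0, omega, tau) {
  b <- p0
  a <- if (is.finite(tau)) (v0 + p0 / tau) / omega else v0 / omega
  c(a, b)
}

#' Score a trajectory against the task geometry
#'
#' Computes the minimal center-to-center distance `d` between ball and target
#' over the flight, and whether the ball contacted the central post. The
#' scan stops at the first post contact: samples at or after contact do not
#' contribute to `d`. Contact is declared when the ball center comes within
#' `post_radius + ball_radius` of the post center (the circles touch).
#'
#' @param traj an `sk_trajectory` from [simulate_flight()].
#' @param geometry a [task_geometry()] object.
#' @return list with `d` (m) and `post_hit` (logical). `d` is `Inf` when the
#'   very first sample already contacts the post.
#' @export
score_trajectory <- function(traj, geometry = task_geometry()) {
  if (is.null(traj$positions) || nrow(traj$positions) == 0)
    stop("empty trajectory", call. = FALSE)
  rel <- sweep(traj$positions, 2, geometry$post_center, "-")
  dpost2 <- rel[, 1]^2 + rel[, 2]^2
  contact <- dpost2 <= (geometry$post_radius + geometry$ball_radius)^2
  post_hit <- any(contact)
  n <- if (post_hit) which(contact)[1] - 1L else nrow(traj$positions)
  if (n < 1L) return(list(d = Inf, post_hit = TRUE))
  dx <- traj$positions[1:n, 1] - geometry$target_center[1]
  dy <- traj$positions[1:n, 2] - geometry$target_center[2]
  list(d = sqrt(min(dx^2 + dy^2)), post_hit = post_hit)
}

#' Classify a trial from its minimal distance and post contact
#'
#' A trial is a hit when `d <= 0.10` m (ball and target radii are 0.05 m
#' each, so the circles overlap) and the post was not contacted; otherwise a
#' miss. For event-related potential averaging only unambiguous trials are
#' used: `d <= 0.07` m counts as a clear hit and `d >= 0.12` m as a clear
#' error; trials in between, and all post-contact trials, are excluded.
#' All boundaries are inclusive.
#'
#' @param d minimal center-to-center ball-target distance (m), >= 0.
#' @param post_hit logical, whether the post was contacted.
#' @param thresholds named list with `hit`, `clear_hit`, `clear_error` (m).
#' @return list with `outcome` (`"hit"`/`"miss"`) and `erp_class`
#'   (`"clear_hit"`/`"clear_error"`/`"excluded"`).
#' @examples
#' classify_trial(0.05, FALSE)
#' classify_trial(0.11, FALSE)
#' @export
classify_trial <- function(d, post_hit,
                           thresholds = list(hit = 0.10, clear_hit = 0.07,
                                             clear_error = 0.12)) {
  if (is.na(d) || d < 0) stop("d must be >= 0", call. = FALSE)
  outcome <- if (!post_hit && d <= thresholds$hit) "hit" else "miss"
  erp_class <- if (post_hit) {
    "excluded"
  } else if (d <= thresholds$clear_hit) {
    "clear_hit"
  } else if (d >= thresholds$clear_error) {
    "clear_error"
  } else {
    "excluded"
  }
  list(outcome = outcome, erp_class = erp_class)
}

#' Detect movement onset from lever angular velocity
#'
#' The movement counts as started at the first sample, strictly after the
#' lever has been in the starting position, at which the absolute angular
#' velocity exceeds 50 degrees/s (strict inequality; a sample at exactly
#' 50 degrees/s does not trigger onset).
#'
#' @param angular_velocity numeric vector, lever angular velocity
#'   (degrees/s) over time.
#' @param in_start_position logical vector of the same length, whether the
#'   lever tip is inside the start circle.
#' @param threshold onset threshold (degrees/s), default 50.
#' @return 1-based onset sample index, or `NA_integer_` when the threshold
#'   is never exceeded after a start-position interval.
#' @examples
#' detect_movement_onset(c(0, 0, 60, 80), c(TRUE, TRUE, FALSE, FALSE))
#' @export
detect_movement_onset <- function(angular_velocity, in_start_position,
                                  threshold = 50) {
  if (length(angular_velocity) == 0) stop("empty series", call. = FALSE)
  if (length(angular_velocity) != length(in_start_position))
    stop("series must be aligned and of equal length", call. = FALSE)
  seen_start <- cumsum(in_start_position) > 0
  # strictly after a start interval: the start sample itself cannot be onset
  candidate <- abs(angular_velocity) > threshold &
    c(FALSE, seen_start[-length(seen_start)])
  idx <- which(candidate)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Hit rate of a set of trials
#'
#' @param trials data.frame with an `outcome` column (`"hit"`/`"miss"`).
#' @return hit rate in percent.
#' @examples
#' hit_rate(data.frame(outcome = c("hit", "hit", "miss", "miss")))
#' @export
hit_rate <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0)
    stop("hit_rate needs at least one trial", call. = FALSE)
  100 * sum(trials$outcome == "hit") / nrow(trials)
}

#' Score many release states at once
#'
#' Vectorized equivalent of [simulate_flight()] + [score_trajectory()] for a
#' set of release parameters, used for parameter sweeps and trial
#' generation. Processes the releases in chunks to bound memory.
#'
#' @param angles_deg numeric vector of lever angles (degrees).
#' @param velocities_deg_s numeric vector (same length) of angular
#'   velocities (degrees/s).
#' @param lever,geometry,params task configuration objects.
#' @param chunk chunk size (number of trajectories per block).
#' @return data.frame with columns `angle_deg`, `velocity_deg_s`, `d_m`,
#'   `post_hit`.
#' @export
score_releases <- function(angles_deg, velocities_deg_s,
                           lever = lever_config(),
                           geometry = task_geometry(),
                           params = oscillator_params(), chunk = 500L) {
  stopifnot(length(angles_deg) == length(velocities_deg_s))
  n <- length(angles_deg)
  t <- seq(0, params$flight_duration, by = params$dt)
  nt <- length(t)
  sw <- sin(params$omega * t); cw <- cos(params$omega * t)
  decay <- if (is.finite(params$tau)) exp(-t / params$tau) else rep(1, nt)
  sw <- sw * decay; cw <- cw * decay
  d_out <- numeric(n); post_out <- logical(n)
  contact2 <- (geometry$post_radius + geometry$ball_radius)^2
  tgt <- geometry$target_center - geometry$post_center
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    th <- angles_deg[lo:hi] * pi / 180
    w <- velocities_deg_s[lo:hi] * pi / 180
    px <- -lever$length * cos(th) + lever$pivot[1] - geometry$post_center[1]
    py <- lever$length * sin(th) + lever$pivot[2] - geometry$post_center[2]
    vx <- lever$length * w * sin(th)
    vy <- lever$length * w * cos(th)
    itau <- if (is.finite(params$tau)) 1 / params$tau else 0
    ax <- (vx + px * itau) / params$omega
    ay <- (vy + py * itau) / params$omega
    X <- ax %o% sw + px %o% cw
    Y <- ay %o% sw + py %o% cw
    P <- X * X + Y * Y <= contact2
    anyc <- rowSums(P) > 0L
    first <- rep(nt + 1L, nrow(P))
    first[anyc] <- max.col(P[anyc, , drop = FALSE], ties.method = "first")
    D <- (X - tgt[1])^2 + (Y - tgt[2])^2
    D[col(D) >= first[row(D)]] <- Inf
    d_out[lo:hi] <- sqrt(apply(D, 1, min))
    post_out[lo:hi] <- anyc
  }
  data.frame(angle_deg = angles_deg, velocity_deg_s = velocities_deg_s,
             d_m = d_out, post_hit = post_out)
}

#' Grid sweep of minimal distance over release parameters
#'
#' Evaluates `d` and post contact over an angle-by-velocity grid.
#'
#' @param angles_deg vector of lever angles (degrees).
#' @param velocities_deg_s vector of angular velocities (degrees/s).
#' @param ... passed to [score_releases()].
#' @return data.frame in long format, one row per grid point, with
#'   `angle_deg`, `velocity_deg_s`, `d_m`, `post_hit`, `outcome`,
#'   `erp_class`.
#' @export
sweep_release_grid <- function(angles_deg, velocities_deg_s, ...) {
  grid <- expand.grid(angle_deg = angles_deg,
                      velocity_deg_s = velocities_deg_s,
                      KEEP.OUT.ATTRS = FALSE)
  res <- score_releases(grid$angle_deg, grid$velocity_deg_s, ...)
  cls <- classify_trials(res$d_m, res$post_hit)
  res$outcome <- cls$outcome
  res$erp_class <- cls$erp_class
  res
}

# vectorized classify_trial
classify_trials <- function(d, post_hit,
                            thresholds = list(hit = 0.10, clear_hit = 0.07,
                                              clear_error = 0.12)) {
  if (any(is.na(d) | d < 0)) stop("d must be >= 0", call. = FALSE)
  outcome <- ifelse(!post_hit & d <= thresholds$hit, "hit", "miss")
  erp_class <- ifelse(post_hit, "excluded",
               ifelse(d <= thresholds$clear_hit, "clear_hit",
               ifelse(d >= thresholds$clear_error, "clear_error", "excluded")))
  list(outcome = outcome, erp_class = erp_class)
}
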