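#' Task geometry of the semi-virtual throwing task
#'
#' Defines the playing field in model (not screen) coordinates: a central
#' post that the ball must travel around, and a target on the far side.
#' Units are meters throughout. The defaults are the standard layout of the
#' task: post of radius 0.25 m at the origin, target of radius 0.05 m at
#' (0.35, 1.0), ball of radius 0.05 m.
#'
#' @param post_center numeric length-2, center of the post (m).
#' @param post_radius post radius (m), > 0.
#' @param target_center numeric length-2, center of the target (m).
#' @param target_radius target radius (m), > 0.
#' @param ball_radius ball radius (m), > 0.
#' @return An object of class `sk_geometry`.
#' @examples
#' geom <- task_geometry()
#' geom$target_center
#' @export
task_geometry <- function(post_center = c(0, 0), post_radius = 0.25,
                          target_center = c(0.35, 1.0), target_radius = 0.05,
                          ball_radius = 0.05) {
  stopifnot(length(post_center) == 2, length(target_center) == 2)
  if (!all(is.finite(c(post_center, target_center))))
    stop("geometry centers must be finite", call. = FALSE)
  if (!(post_radius > 0 && target_radius > 0 && ball_radius > 0))
    stop("all radii must be > 0", call. = FALSE)
  structure(list(post_center = as.numeric(post_center),
                 post_radius = post_radius,
                 target_center = as.numeric(target_center),
                 target_radius = target_radius,
                 ball_radius = ball_radius),
            class = "sk_geometry")
}

#' Lever (manipulandum) configuration
#'
#' The virtual lever rotates in the horizontal plane about a fixed pivot.
#' Angle convention (used consistently everywhere in the package): at 0 deg
#' the lever tip lies on the negative-x side of the pivot (the start circle),
#' and the angle increases in the clockwise sense of the screen frame
#' (target toward +y). At 90 deg the tip points toward +y from the pivot.
#'
#' @param pivot numeric length-2, position of the fixed end (m).
#' @param length lever length (m), > 0.
#' @return An object of class `sk_lever`.
#' @examples
#' lever_config()
#' @export
lever_config <- function(pivot = c(0, -1.5), length = 0.4) {
  stopifnot(base::length(pivot) == 2)
  if (!all(is.finite(pivot)) || !is.finite(length) || length <= 0)
    stop("invalid lever configuration", call. = FALSE)
  structure(list(pivot = as.numeric(pivot), length = length),
            class = "sk_lever")
}

#' Ball-flight oscillator parameters
#'
#' The ball flight is modeled as a two-dimensional isotropic damped harmonic
#' restoring force about the post center, giving the elliptic paths around
#' the post that the task displays. `omega` is the angular frequency of the
#' restoring force and `tau` the exponential amplitude-decay constant
#' (`tau = Inf` for undamped flight). Defaults are chosen so that a typical
#' successful throw reaches the vicinity of the target about 0.85 s after
#' release, the delay at which outcome feedback is presented.
#'
#' @param omega angular frequency (rad/s), > 0.
#' @param tau amplitude decay constant (s), > 0 or `Inf`.
#' @param flight_duration simulated flight length (s), > 0.
#' @param dt sample step (s), > 0; default 0.002 s matches the 500 Hz
#'   recording clock.
#' @return An object of class `sk_oscillator`.
#' @examples
#' oscillator_params()
#' @export
oscillator_params <- function(omega = 3.0, tau = 10, flight_duration = 2,
                              dt = 0.002) {
  if (!is.finite(omega) || omega <= 0) stop("omega must be > 0", call. = FALSE)
  if (is.na(tau) || tau <= 0) stop("tau must be > 0 (or Inf)", call. = FALSE)
  if (!is.finite(flight_duration) || flight_duration <= 0 ||
      !is.finite(dt) || dt <= 0)
    stop("flight_duration and dt must be > 0", call. = FALSE)
  structure(list(omega = omega, tau = tau,
                 flight_duration = flight_duration, dt = dt),
            class = "sk_oscillator")
}

# unit direction of the lever tip at `angle_deg` under the package convention
lever_direction <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(-cos(th), sin(th))
}

#' Release state from lever angle and angular velocity
#'
#' Computes ball position and velocity at the moment of release. The ball
#' sits at the lever tip and leaves with a purely tangential velocity in the
#' clockwise rotation sense; its speed is the angular velocity (in rad/s)
#' times the lever length.
#'
#' @param lever_angle lever angle at release (degrees, in `[0, 360)`).
#' @param lever_angular_velocity angular velocity at release (degrees/s).
#' @param lever an [lever_config()] object.
#' @return An object of class `sk_release` with fields `lever_angle`,
#'   `lever_angular_velocity`, `ball_position` (m), `ball_velocity` (m/s).
#' @examples
#' release_state(90, 180)
#' @export
release_state <- function(lever_angle, lever_angular_velocity,
                          lever = lever_config()) {
  if (!is.finite(lever_angle) || !is.finite(lever_angular_velocity))
    stop("release parameters must be finite", call. = FALSE)
  if (lever_angle < 0 || lever_angle >= 360)
    stop("lever_angle must lie in [0, 360) degrees", call. = FALSE)
  th <- lever_angle * pi / 180
  w <- lever_angular_velocity * pi / 180
  pos <- lever$pivot + lever$length * lever_direction(lever_angle)
  # d(direction)/d(theta) = (sin, cos); tangential speed = |w| * length
  vel <- lever$length * w * c(sin(th), cos(th))
  structure(list(lever_angle = lever_angle,
                 lever_angular_velocity = lever_angular_velocity,
                 ball_position = pos, ball_velocity = vel),
            class = "sk_release")
}
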