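#' Specification of an injectable ERP component
#'
#' Describes a transient deflection locked to a trial event, used by the
#' synthetic EEG generator. The two canonical components of the task are the
#' error-related negativity (Ne/ERN; release-locked, 200-350 ms) and the
#' feedback-related negativity (FRN; feedback-locked, 150-350 ms), both
#' negative on error trials.
#'
#' Shapes: `"half_cosine"` is a raised cosine arch over the window (window
#' mean = peak * 2/pi); `"gaussian"` is a Gaussian bump centered in the
#' window, truncated at +/- 3 sigma with `sigma = width/6` (window mean =
#' peak * sqrt(2*pi)/6 * (2*pnorm(3) - 1)).
#'
#' @param lock_event `"release"` or `"feedback"`.
#' @param window length-2 numeric, window start/end in ms relative to the
#'   lock event.
#' @param peak_amplitude peak amplitude in microvolts (negative for
#'   Ne/ERN-like deflections).
#' @param shape `"half_cosine"` or `"gaussian"`.
#' @param applies_to `"error_trials"` (default) or `"all_trials"`.
#' @return An object of class `sk_component`.
#' @examples
#' erp_component("release", c(200, 350), -0.6)
#' @export
erp_component <- function(lock_event = c("release", "feedback"),
                          window, peak_amplitude,
                          shape = c("half_cosine", "gaussian"),
                          applies_to = c("error_trials", "all_trials")) {
  lock_event <- match.arg(lock_event)
  shape <- match.arg(shape)
  applies_to <- match.arg(applies_to)
  stopifnot(length(window) == 2)
  if (!(window[1] < window[2])) stop("window start must precede end",
                                     call. = FALSE)
  if (!is.finite(peak_amplitude)) stop("peak_amplitude must be finite",
                                       call. = FALSE)
  structure(list(lock_event = lock_event, window = as.numeric(window),
                 peak_amplitude = peak_amplitude, shape = shape,
                 applies_to = applies_to),
            class = "sk_component")
}

#' Evaluate a component waveform
#'
#' Returns the component amplitude at times `t_ms` relative to its lock
#' event. Zero outside the window; the peak amplitude is reached exactly at
#' the window midpoint.
#'
#' @param spec an [erp_component()].
#' @param t_ms numeric vector of times (ms) relative to the lock event.
#' @return numeric vector of amplitudes (microvolts).
#' @examples
#' spec <- erp_component("release", c(200, 350), -1)
#' component_waveform(spec, c(100, 275, 400))
#' @export
component_waveform <- function(spec, t_ms) {
  a <- spec$window[1]; b <- spec$window[2]
  width <- b - a; mid <- (a + b) / 2
  inside <- t_ms >= a & t_ms <= b
  out <- numeric(length(t_ms))
  if (spec$shape == "half_cosine") {
    out[inside] <- spec$peak_amplitude * cos(pi * (t_ms[inside] - mid) / width)
  } else {
    sigma <- width / 6
    out[inside] <- spec$peak_amplitude *
      exp(-((t_ms[inside] - mid)^2) / (2 * sigma^2))
  }
  out
}

# unit-peak waveform (shape only), used when injecting drawn amplitudes
component_unit_waveform <- function(spec, t_ms) {
  unit <- spec
  unit$peak_amplitude <- 1
  component_waveform(unit, t_ms)
}

#' Analytic window mean of a component shape
#'
#' Closed-form mean of the component waveform over its own window, as a
#' fraction of the peak amplitude: `2/pi` for the half-cosine arch;
#' `sqrt(2*pi)/6 * (2*pnorm(3) - 1)` for the truncated Gaussian.
#'
#' @param spec an [erp_component()], or a shape name.
#' @return the shape factor (unitless).
#' @examples
#' component_shape_factor(erp_component("release", c(200, 350), -1))
#' @export
component_shape_factor <- function(spec) {
  shape <- if (inherits(spec, "sk_component")) spec$shape else spec
  switch(shape,
         half_cosine = 2 / pi,
         gaussian = sqrt(2 * pi) / 6 * (2 * stats::pnorm(3) - 1),
         stop("unknown shape: ", shape, call. = FALSE))
}
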