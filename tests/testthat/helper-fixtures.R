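# shared fixtures built in code

quietly <- function(expr) suppressMessages(expr)

# noise-free, no between-participant variability; used for exact recovery
noise_free_design <- function(condition, n_participants = 3,
                              trials_per_participant = 24) {
  cohort_design(condition, n_participants = n_participants,
                trials_per_participant = trials_per_participant,
                noise = list(pink_sd = 0, white_sd = 0, alpha = 1,
                             f_floor = 0.25),
                between_participant_amplitude_sd = 0)
}

# scaled-down configuration for fast end-to-end runs
small_config <- function() {
  cfg <- default_config()
  cfg$conditions$Visual$n_participants <- 4
  cfg$conditions$Visual$trials_per_participant <- 20
  cfg$conditions$EffProp$n_participants <- 4
  cfg$conditions$EffProp$trials_per_participant <- 40
  cfg$practice$n_participants <- 4
  cfg$practice$trials_per_session <- 50
  cfg
}

# a minimal sk_epochs object with arbitrary data, release offset 0
make_epochs <- function(data_matrix, fs = 500, start_ms = -100,
                        erp_class = NULL) {
  n_ep <- nrow(data_matrix); nt <- ncol(data_matrix)
  k0 <- round(start_ms / 1000 * fs)
  arr <- array(0, dim = c(n_ep, nt, 1), dimnames = list(NULL, NULL, "FCz"))
  arr[, , 1] <- data_matrix
  if (is.null(erp_class))
    erp_class <- rep(c("clear_error", "clear_hit"), length.out = n_ep)
  structure(list(
    data = arr, times_ms = (k0:(k0 + nt - 1)) / fs * 1000,
    channels = "FCz", fs = fs,
    info = data.frame(trial_id = seq_len(n_ep),
                      outcome = ifelse(erp_class == "clear_hit",
                                       "hit", "miss"),
                      erp_class = erp_class,
                      release_offset = 0L,
                      feedback_offset = as.integer(round(0.85 * fs)),
                      rejected = FALSE),
    anchor = "S_release", participant_id = 1L, condition = "EffProp",
    n_dropped_edge = 0L), class = "sk_epochs")
}

# a difference wave built directly from two curves on standard grids
make_wave <- function(release_amp, feedback_amp, fs = 500,
                      release_start_ms = -600, feedback_start_ms = -600) {
  rel_t <- release_start_ms + (seq_along(release_amp) - 1) * 1000 / fs
  fb_t <- feedback_start_ms + (seq_along(feedback_amp) - 1) * 1000 / fs
  structure(list(release = list(times_ms = rel_t, amplitude = release_amp),
                 feedback = list(times_ms = fb_t, amplitude = feedback_amp),
                 n_error = 1L, n_hit = 1L, participant_id = NA),
            class = "sk_diffwave")
}

# independent Runge-Kutta oracle for the flight dynamics:
# x'' = -(omega^2 + 1/tau^2) x - (2/tau) x'
ode_flight_oracle <- function(release, params, geometry = task_geometry(),
                              times) {
  deriv <- function(t, y, p) {
    list(c(y[3], y[4],
           -(p$omega^2 + p$itau^2) * y[1] - 2 * p$itau * y[3],
           -(p$omega^2 + p$itau^2) * y[2] - 2 * p$itau * y[4]))
  }
  itau <- if (is.finite(params$tau)) 1 / params$tau else 0
  y0 <- c(release$ball_position - geometry$post_center,
          release$ball_velocity)
  sol <- deSolve::ode(y0, times, deriv,
                      list(omega = params$omega, itau = itau),
                      method = "ode45", rtol = 1e-10, atol = 1e-12)
  sweep(sol[, 2:3, drop = FALSE], 2, geometry$post_center, "+")
}

# end-to-end runs are expensive; share them across test blocks
.run_cache <- new.env(parent = emptyenv())
cached_small_run <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- quietly(run_pipeline(small_config(), seed = seed))
  .run_cache[[key]]
}
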