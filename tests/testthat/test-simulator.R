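test_that("release geometry follows the lever convention", {
  r0 <- release_state(0, 0)
  expect_equal(r0$ball_position, c(-0.4, -1.5))
  expect_equal(r0$ball_velocity, c(0, 0))

  r90 <- release_state(90, 180)
  expect_equal(r90$ball_position, c(0, -1.1))
  expect_equal(sqrt(sum(r90$ball_velocity^2)), pi * 0.4, tolerance = 1e-12)

  # speed is linear in angular velocity
  v1 <- sqrt(sum(release_state(37, 120)$ball_velocity^2))
  v2 <- sqrt(sum(release_state(37, 240)$ball_velocity^2))
  expect_equal(v2, 2 * v1, tolerance = 1e-12)

  expect_error(release_state(NaN, 100), "finite")
  expect_error(release_state(10, Inf), "finite")
  expect_error(release_state(360, 100), "\\[0, 360\\)")
})

test_that("undamped flight is periodic and damped flight decays", {
  # omega chosen so one period (1 s) is a whole number of 2 ms steps
  params <- oscillator_params(omega = 2 * pi, tau = Inf, flight_duration = 2)
  traj <- simulate_flight(release_state(80, 300), params)
  i_period <- which.min(abs(traj$times - 1))
  expect_equal(traj$positions[i_period, ], traj$positions[1, ],
               tolerance = 1e-9)

  damped <- simulate_flight(release_state(80, 300),
                            oscillator_params(omega = 2 * pi, tau = 2,
                                              flight_duration = 3))
  r <- sqrt(rowSums(damped$positions^2))
  per <- 500L  # samples per period
  env <- vapply(0:2, function(k) max(r[(k * per + 1):((k + 1) * per)]), 0)
  expect_true(all(diff(env) < 0))
})

test_that("closed-form flight matches an independent Runge-Kutta oracle", {
  set.seed(11)
  params <- oscillator_params()
  for (i in 1:10) {
    rel <- release_state(runif(1, 20, 160), runif(1, 80, 600))
    traj <- simulate_flight(rel, params)
    oracle <- ode_flight_oracle(rel, params, times = traj$times)
    expect_lt(max(abs(traj$positions - oracle)), 1e-6)
  }
})

test_that("degenerate release at the post center errors", {
  rel <- structure(list(ball_position = c(0, 0), ball_velocity = c(0, 0)),
                   class = "sk_release")
  expect_error(simulate_flight(rel), "degenerate")
})

test_that("trajectory scoring measures d and post contact", {
  # straight synthetic path through the target center
  y <- seq(0.5, 1.5, by = 0.01)
  through_target <- structure(list(times = seq_along(y) * 0.002 - 0.002,
                                   positions = cbind(0.35, y)),
                              class = "sk_trajectory")
  sc <- score_trajectory(through_target)
  expect_equal(sc$d, 0)
  expect_false(sc$post_hit)

  # straight path through the origin contacts the post at 0.30 m
  y2 <- seq(-1, 1, by = 0.01)
  through_post <- structure(list(times = seq_along(y2) * 0.002 - 0.002,
                                 positions = cbind(0, y2)),
                            class = "sk_trajectory")
  expect_true(score_trajectory(through_post)$post_hit)

  expect_error(score_trajectory(structure(list(
    times = numeric(), positions = matrix(0, 0, 2)),
    class = "sk_trajectory")), "empty")
})

test_that("d is stable under time-grid refinement", {
  rel <- release_state(84, 320)
  coarse <- simulate_flight(rel, oscillator_params(dt = 0.002))
  fine <- simulate_flight(rel, oscillator_params(dt = 1e-4))
  d_coarse <- score_trajectory(coarse)$d
  d_fine <- score_trajectory(fine)$d
  v_max <- max(sqrt(rowSums((diff(fine$positions) / 1e-4)^2)))
  expect_lt(abs(d_coarse - d_fine), v_max * 0.002)
})

test_that("trial classification applies the inclusive thresholds", {
  expect_equal(classify_trial(0.05, FALSE),
               list(outcome = "hit", erp_class = "clear_hit"))
  expect_equal(classify_trial(0.11, FALSE),
               list(outcome = "miss", erp_class = "excluded"))
  expect_equal(classify_trial(0.15, FALSE),
               list(outcome = "miss", erp_class = "clear_error"))
  expect_equal(classify_trial(0.05, TRUE),
               list(outcome = "miss", erp_class = "excluded"))
  # boundaries: 0.07 and 0.10 and 0.12 are all inclusive
  expect_equal(classify_trial(0.07, FALSE),
               list(outcome = "hit", erp_class = "clear_hit"))
  expect_equal(classify_trial(0.10, FALSE),
               list(outcome = "hit", erp_class = "excluded"))
  expect_equal(classify_trial(0.12, FALSE),
               list(outcome = "miss", erp_class = "clear_error"))
  expect_error(classify_trial(-0.01, FALSE), ">= 0")
})

test_that("movement onset uses a strict 50 deg/s threshold after start", {
  expect_true(is.na(detect_movement_onset(rep(0, 10), rep(TRUE, 10))))
  expect_identical(detect_movement_onset(c(0, 0, 60, 80),
                                         c(TRUE, TRUE, FALSE, FALSE)), 3L)
  expect_true(is.na(detect_movement_onset(c(0, 0, 50, 50),
                                          c(TRUE, TRUE, FALSE, FALSE))))
  # velocity burst before ever reaching the start position does not count
  expect_identical(detect_movement_onset(c(80, 0, 0, 80),
                                         c(FALSE, TRUE, TRUE, FALSE)), 4L)
  expect_error(detect_movement_onset(numeric(), logical()), "empty")
  expect_error(detect_movement_onset(c(1, 2), TRUE), "equal length")
})

test_that("hit rate equals an independent recount", {
  expect_equal(hit_rate(data.frame(outcome = rep("hit", 5))), 100)
  expect_equal(hit_rate(data.frame(outcome = c("hit", "hit", "miss",
                                               "miss"))), 50)
  set.seed(3)
  tr <- simulate_trials(1000)
  recount <- 0L
  for (i in seq_len(nrow(tr)))
    if (identical(tr$outcome[i], "hit")) recount <- recount + 1L
  expect_equal(hit_rate(tr), 100 * recount / 1000)
  expect_error(hit_rate(tr[0, ]), "at least one")
})

test_that("vectorized scoring agrees with per-trajectory simulation", {
  set.seed(21)
  ang <- runif(25, 30, 150); vel <- runif(25, 80, 600)
  vec <- score_releases(ang, vel)
  for (i in seq_along(ang)) {
    sc <- score_trajectory(simulate_flight(release_state(ang[i], vel[i])))
    expect_equal(vec$d_m[i], sc$d, tolerance = 1e-12)
    expect_identical(vec$post_hit[i], sc$post_hit)
  }
})

test_that("d varies smoothly along a post-free slice of release space", {
  ang <- seq(70, 78, by = 0.1)
  res <- score_releases(ang, rep(300, length(ang)))
  expect_false(any(res$post_hit))
  expect_lt(max(abs(diff(res$d_m))), 0.01)
})

test_that("classification partitions release space", {
  grid <- sweep_release_grid(seq(30, 150, length.out = 40),
                             seq(80, 600, length.out = 40))
  expect_true(all(grid$outcome %in% c("hit", "miss")))
  expect_true(all(grid$erp_class %in% c("clear_hit", "clear_error",
                                        "excluded")))
  expect_true(all(grid$outcome[grid$erp_class == "clear_hit"] == "hit"))
  expect_true(all(grid$outcome[grid$erp_class == "clear_error"] == "miss"))
})

test_that("simulated sessions have plausible composition and timing", {
  set.seed(9)
  tr <- simulate_trials(120)
  expect_true(hit_rate(tr) > 40 && hit_rate(tr) < 95)
  expect_equal(tr$t_feedback_s - tr$t_release_s, rep(0.85, 120))
  expect_true(all(diff(tr$t_start_s) > 0))

  # balanced observation set: hit and miss counts within one trial
  trv <- simulate_trials(51, condition = "Visual", error_fraction = 0.5)
  expect_lte(abs(sum(trv$outcome == "hit") - sum(trv$outcome == "miss")), 1)
  expect_false(any(trv$post_hit))
})
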