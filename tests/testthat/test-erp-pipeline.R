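make_test_recording <- function(samples, fs = 500, markers = NULL) {
  structure(list(samples = samples,
                 channels = colnames(samples), fs = fs,
                 markers = markers %||%
                   data.frame(type = character(), trial_id = integer(),
                              sample = integer()),
                 participant_id = 1L, condition = "EffProp"),
            class = "sk_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("band-pass filtering behaves like a 0.2-30 Hz Butterworth", {
  n <- 10000; fs <- 500
  zeros <- matrix(0, n, 3, dimnames = list(NULL, c("FCz", "M1", "M2")))
  rec0 <- preprocess(make_test_recording(zeros))
  expect_true(all(rec0$samples == 0))

  t <- (0:(n - 1)) / fs
  sine50 <- matrix(sin(2 * pi * 50 * t), n, 1, dimnames = list(NULL, "FCz"))
  out <- preprocess(make_test_recording(sine50), reference = "none")
  mid <- 2000:8000
  expect_lt(sqrt(mean(out$samples[mid, 1]^2)),
            0.25 * sqrt(mean(sine50[mid, 1]^2)))

  dc <- matrix(10, n, 1, dimnames = list(NULL, "FCz"))
  outdc <- preprocess(make_test_recording(dc), reference = "none")
  expect_lt(max(abs(outdc$samples[5000:6000, 1])), 0.5)

  expect_error(preprocess(make_test_recording(sine50)),
               "mastoid")
  expect_error(preprocess(make_test_recording(zeros),
                          filter = list(low = 0.2, high = 300, order = 2),
                          reference = "none"),
               "Nyquist")
})

test_that("mastoid re-referencing subtracts the mastoid average", {
  n <- 100
  x <- cbind(FCz = rnorm(n), M1 = rnorm(n), M2 = rnorm(n))
  rec <- preprocess(make_test_recording(x), filter = NULL)
  expect_equal(rec$samples[, "FCz"], x[, "FCz"] - (x[, "M1"] + x[, "M2"]) / 2)
})

test_that("epochs cover the prescribed sample window around the anchor", {
  n <- 20000
  samples <- matrix(seq_len(n), n, 1, dimnames = list(NULL, "FCz"))
  markers <- data.frame(
    type = c("S_trialstart", "S_release", "S_feedback"),
    trial_id = 1L, sample = c(9500L, 10000L, 10425L))
  rec <- make_test_recording(samples, markers = markers)
  trials <- data.frame(trial_id = 1L, outcome = "miss",
                       erp_class = "clear_error")
  ep <- segment_epochs(rec, trials, segment_spec("EffProp"))
  # -600..+2200 ms at 500 Hz around sample 10000 = samples 9700..11100
  expect_equal(dim(ep$data), c(1, 1401, 1))
  expect_equal(ep$data[1, , 1], as.numeric(9700:11100))
  expect_equal(ep$info$release_offset, 0)
  expect_equal(ep$info$feedback_offset, 425)
})

test_that("epochs beyond the recording edge are dropped and logged", {
  samples <- matrix(rnorm(6000), 6000, 1, dimnames = list(NULL, "FCz"))
  markers <- data.frame(
    type = rep(c("S_trialstart", "S_release", "S_feedback"), 2),
    trial_id = rep(1:2, each = 3),
    sample = c(900L, 1400L, 1825L, 5300L, 5800L, 6225L))
  rec <- make_test_recording(samples, markers = markers)
  trials <- data.frame(trial_id = 1:2, outcome = "miss",
                       erp_class = "clear_error")
  expect_message(
    ep <- segment_epochs(rec, trials, segment_spec("EffProp")),
    "dropped")
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(ep$n_dropped_edge, 1L)
  # missing marker is a consistency error
  expect_error(segment_epochs(rec, data.frame(trial_id = 3,
                                              outcome = "miss",
                                              erp_class = "clear_error"),
                              segment_spec("EffProp")),
               "consistency")
})

test_that("artifact rejection flags epochs exceeding the threshold", {
  set.seed(51)
  clean <- matrix(rnorm(20 * 500, 0, 10), 20, 500)
  ep <- reject_artifacts(make_epochs(clean))
  expect_equal(sum(ep$info$rejected), 0)

  dirty <- clean
  dirty[7, 100] <- 500
  dirty[13, 300] <- -250
  ep2 <- quietly(reject_artifacts(make_epochs(dirty)))
  brute <- vapply(seq_len(20), function(e) any(abs(dirty[e, ]) > 100),
                  logical(1))
  expect_identical(ep2$info$rejected, brute)
  expect_error(reject_artifacts(make_epochs(clean), threshold = 0), "> 0")
})

test_that("baseline correction zeroes the baseline and is idempotent", {
  const <- matrix(5, 4, 400)
  ep <- baseline_correct(make_epochs(const))
  expect_true(all(ep$data == 0))

  set.seed(52)
  noisy <- make_epochs(matrix(rnorm(4 * 400), 4, 400))
  once <- baseline_correct(noisy)
  twice <- baseline_correct(once)
  expect_equal(once$data, twice$data, tolerance = 1e-14)
  sel <- which(once$times_ms >= 0 & once$times_ms < 200)
  for (e in 1:4)
    expect_equal(mean(once$data[e, sel, 1]), 0, tolerance = 1e-13)
})

test_that("outcome averages are plain means over marker-aligned epochs", {
  set.seed(53)
  dat <- matrix(rnorm(6 * 1500), 6, 1500)
  ep <- make_epochs(dat, start_ms = -600)
  av <- outcome_averages(ep, release_span_ms = c(-200, 800),
                         feedback_span_ms = c(-400, 398))
  err_rows <- which(ep$info$erp_class == "clear_error")
  sel <- which(ep$times_ms >= -200 - 1e-9 & ep$times_ms <= 800 + 1e-9)
  expect_equal(av$error$release$amplitude,
               colMeans(dat[err_rows, sel, drop = FALSE]),
               tolerance = 1e-12)
  # permutation invariance
  perm <- sample(6)
  ep_perm <- make_epochs(dat[perm, ], start_ms = -600,
                         erp_class = ep$info$erp_class[perm])
  av2 <- outcome_averages(ep_perm, release_span_ms = c(-200, 800),
                          feedback_span_ms = c(-400, 398))
  expect_equal(av$error$release$amplitude, av2$error$release$amplitude,
               tolerance = 1e-12)
  # a participant without one class is rejected
  ep_onesided <- make_epochs(dat, start_ms = -600,
                             erp_class = rep("clear_hit", 6))
  expect_error(outcome_averages(ep_onesided), "lacks")
})

test_that("difference waves subtract pointwise and are antisymmetric", {
  set.seed(54)
  a <- list(release = list(times_ms = 0:99, amplitude = rnorm(100)),
            feedback = list(times_ms = 0:49, amplitude = rnorm(50)), n = 3)
  b <- list(release = list(times_ms = 0:99, amplitude = rnorm(100)),
            feedback = list(times_ms = 0:49, amplitude = rnorm(50)), n = 4)
  w_ab <- difference_wave(a, b)
  w_ba <- difference_wave(b, a)
  expect_equal(w_ab$release$amplitude, a$release$amplitude -
                 b$release$amplitude)
  expect_equal(w_ab$release$amplitude, -w_ba$release$amplitude)
  expect_equal(w_ab$feedback$amplitude, -w_ba$feedback$amplitude)
  w_aa <- difference_wave(a, a)
  expect_true(all(w_aa$release$amplitude == 0))
})

test_that("window statistics: mean, minimum-as-peak, half-open edges", {
  # constant wave
  wave <- make_wave(rep(-1, 1000), rep(-1, 600))
  ws <- window_stats(wave)
  expect_equal(ws$mean_uV, c(-1, -1))
  expect_equal(ws$peak_uV, c(-1, -1))

  # negative cosine arch spanning the Ne/ERN window: mean = peak * 2/pi
  rel_t <- seq(-600, 1348, by = 2)
  arch <- ifelse(rel_t >= 200 & rel_t <= 350,
                 -cos(pi * (rel_t - 275) / 150), 0)
  wave2 <- make_wave(arch, rep(0, 600))
  ws2 <- window_stats(wave2)
  ern <- ws2[ws2$window == "effw_ern", ]
  expect_equal(ern$mean_uV, ern$peak_uV * 2 / pi, tolerance = 1e-3)

  # peak (minimum) never exceeds the mean
  set.seed(55)
  for (i in 1:50) {
    w <- make_wave(rnorm(1000), rnorm(600))
    s <- window_stats(w)
    expect_true(all(s$peak_uV <= s$mean_uV))
  }

  # window outside the wave span errors
  short <- make_wave(rnorm(100), rnorm(600))
  expect_error(window_stats(short), "window error")
})

test_that("grand averages are pointwise means with the min-mean property", {
  set.seed(56)
  waves <- lapply(1:8, function(i) make_wave(rnorm(1000), rnorm(600)))
  ga <- grand_average(waves)
  brute <- rowMeans(vapply(waves, function(w) w$release$amplitude,
                           numeric(1000)))
  expect_equal(ga$release$amplitude, brute, tolerance = 1e-12)
  expect_equal(grand_average(waves[1])$release$amplitude,
               waves[[1]]$release$amplitude)
  # mean of per-participant minima <= minimum of the grand-average curve
  sel <- which(ga$release$times_ms >= 200 & ga$release$times_ms < 350)
  per_min <- vapply(waves, function(w) min(w$release$amplitude[sel]), 0)
  expect_lte(mean(per_min), min(ga$release$amplitude[sel]))
})

test_that("baseline correction and averaging commute for shared offsets", {
  set.seed(57)
  dat <- matrix(rnorm(6 * 800), 6, 800)
  ep <- make_epochs(dat, start_ms = -100,
                    erp_class = rep("clear_error", 6))
  corrected <- baseline_correct(ep)
  mean_then_correct <- colMeans(dat) -
    mean(colMeans(dat)[ep$times_ms >= 0 & ep$times_ms < 200])
  correct_then_mean <- colMeans(corrected$data[, , 1])
  expect_equal(correct_then_mean, mean_then_correct, tolerance = 1e-12)
})
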