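test_that("one-sample t matches the closed form and stats::t.test", {
  res <- one_sample_t(c(-1, -2, -3))
  expect_equal(res$estimate, -2)
  expect_equal(res$t, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$cohens_d, 2)

  sym <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$cohens_d, 0)

  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    mine <- one_sample_t(x)
    ref <- stats::t.test(x)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$ci95, as.numeric(ref$conf.int), tolerance = 1e-10)
  }
  # directional tails
  neg <- one_sample_t(c(-1, -2, -3), tail = "negative")
  expect_equal(neg$p, stats::pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_error(one_sample_t(c(1, 1, 1)), "zero variance")
  expect_error(one_sample_t(2), "at least two")
})

test_that("two-group t reproduces the pooled textbook formula", {
  expect_equal(two_group_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_error(two_group_t(c(0, 0, 0, 0), c(1, 1, 1, 1)), "zero pooled")

  set.seed(62)
  for (i in 1:10) {
    a <- rnorm(18); b <- rnorm(17, 0.3)
    mine <- two_group_t(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, 33)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    refw <- stats::t.test(a, b)
    minew <- two_group_t(a, b, variant = "welch")
    expect_equal(minew$t, unname(refw$statistic), tolerance = 1e-10)
    expect_equal(minew$df, unname(refw$parameter), tolerance = 1e-10)
  }
})

test_that("JZS Bayes factors reproduce an independent implementation", {
  # reference values from a JZS quadrature oracle (Cauchy scale 1/sqrt(2))
  frozen <- list(list(t = -2.4, n = 18, bf = 2.272831988774003),
                 list(t = 2.0, n = 30, bf = 1.110231866969257),
                 list(t = 0.13, n = 17, bf = 0.2508676575052513),
                 list(t = -4.73, n = 17, bf = 137.94243004211754),
                 list(t = 3.2, n = 12, bf = 6.783156400629743))
  for (f in frozen)
    expect_equal(jzs_bayes_factor(f$t, f$n), f$bf, tolerance = 1e-4)
})

test_that("one-sided JZS factors mix to the two-sided factor", {
  for (t in c(-3, -0.8, 0, 1.7, 4)) {
    for (n in c(5, 18, 50)) {
      two <- jzs_bayes_factor(t, n)
      neg <- jzs_bayes_factor(t, n, side = "negative")
      pos <- jzs_bayes_factor(t, n, side = "positive")
      expect_equal(neg + pos, 2 * two, tolerance = 1e-6 * 2 * two)
    }
  }
  expect_lt(jzs_bayes_factor(0, 20), 1)
  # monotone in |t| for fixed n
  bfs <- vapply(seq(0, 8, by = 0.5), jzs_bayes_factor, 0, n = 18)
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bayes_factor(Inf, 10), "finite")
  expect_error(jzs_bayes_factor(1, 1), "n must be")
})

test_that("Bayes factors grow with n under a true effect and shrink under the null", {
  set.seed(63)
  med_bf <- function(n, mu) {
    stats::median(replicate(40, {
      x <- rnorm(n, mu, 1)
      jzs_bayes_factor(one_sample_t(x)$t, n)
    }))
  }
  effect <- vapply(c(18, 50, 200), med_bf, 0, mu = 0.5)
  expect_true(all(diff(effect) > 0))
  null <- vapply(c(18, 50, 200), med_bf, 0, mu = 0)
  expect_true(all(null < 1))
})

test_that("one-way ANOVA matches the between/within decomposition", {
  # equal group means -> F = 0
  res0 <- one_way_anova(c(1, 3, 0, 4), c("a", "a", "b", "b"))
  expect_equal(res0$F, 0, tolerance = 1e-12)

  # two groups: F equals the squared pooled t
  set.seed(64)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  res2 <- one_way_anova(c(a, b), rep(c("a", "b"), c(10, 12)))
  tt <- two_group_t(a, b)
  expect_equal(res2$F, tt$t^2, tolerance = 1e-10)
  expect_equal(res2$df1, 1); expect_equal(res2$df2, 20)

  # formula oracle on random data
  y <- rnorm(30); g <- rep(1:3, each = 10)
  res3 <- one_way_anova(y, g)
  gm <- tapply(y, g, mean)
  ssb <- sum(10 * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.character(g)])^2)
  expect_equal(res3$F, (ssb / 2) / (ssw / 27), tolerance = 1e-10)
  expect_equal(res3$p, stats::pf((ssb / 2) / (ssw / 27), 2, 27,
                                 lower.tail = FALSE), tolerance = 1e-10)
  expect_error(one_way_anova(rep(1, 6), rep(1:2, 3)), "identical")
})

test_that("evidence labels follow the 1/3/20/150 cut points", {
  expect_identical(interpret_bf(5.3), "positive")
  expect_identical(interpret_bf(170), "very strong")
  expect_identical(interpret_bf(1063), "very strong")
  expect_identical(interpret_bf(2.77), "weak")
  expect_identical(interpret_bf(1.99), "weak")
  expect_identical(interpret_bf(0.21), "favors null")
  expect_identical(interpret_bf(c(1, 3, 20, 150)),
                   c("weak", "positive", "strong", "very strong"))
  expect_error(interpret_bf(0), "> 0")
  expect_error(interpret_bf(-2), "> 0")
})

test_that("window inference combines t, CI, BF and label coherently", {
  set.seed(65)
  x <- rnorm(18, -0.6, 1.1)
  inf <- window_inference(x)
  expect_equal(inf$p, stats::pt(inf$t, 17), tolerance = 1e-12)
  expect_equal(inf$bf10,
               jzs_bayes_factor(inf$t, 18, scale = 1 / sqrt(2),
                                side = "negative"), tolerance = 1e-10)
  expect_identical(inf$evidence_label, interpret_bf(inf$bf10))
})

test_that("epoch-level amplitude simulation equals the pipeline route", {
  comps <- list(ern = erp_component("release", c(200, 350), -0.9))
  noise <- list(pink_sd = 6, white_sd = 2, alpha = 1, f_floor = 0.25)
  set.seed(66)
  direct <- simulate_cohort_amplitudes(n_participants = 1, n_error = 5,
                                       n_hit = 5, peak_amplitude = -0.9,
                                       between_sd = 0, noise = noise,
                                       epoch_window_ms = c(-600, 2200))
  set.seed(66)
  ep <- simulate_epoch_set(5, 5, comps, noise = noise,
                           epoch_window_ms = c(-600, 2200))
  ep <- baseline_correct(ep)
  av <- outcome_averages(ep)
  ws <- window_stats(difference_wave(av$error, av$hit))
  expect_equal(direct, ws$mean_uV[ws$window == "effw_ern"],
               tolerance = 1e-10)
})
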