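#' One-sample t-test with effect size and confidence interval
#'
#' Tests whether the mean of per-participant window amplitudes differs from
#' `mu0`. `t = (mean - mu0) / (sd / sqrt(n))` with `df = n - 1`;
#' `cohens_d = |mean - mu0| / sd`. The 95 percent confidence interval is
#' always two-sided, regardless of the test tail. Tail `"negative"` tests the
#' directional hypothesis of a negative deflection (`p = P(T <= t)`).
#'
#' @param values numeric vector (microvolts per participant), `n >= 2`.
#' @param mu0 test value, default 0.
#' @param tail `"two_sided"`, `"negative"`, or `"positive"`.
#' @return An object of class `sk_inference`: list with `estimate`, `t`,
#'   `df`, `p`, `tail`, `cohens_d`, `ci95`, `n`.
#' @examples
#' one_sample_t(c(-1, -2, -3))
#' @export
one_sample_t <- function(values, mu0 = 0,
                         tail = c("two_sided", "negative", "positive")) {
  tail <- match.arg(tail)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least two values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero variance", call. = FALSE)
  m <- mean(values)
  se <- s / sqrt(n)
  t <- (m - mu0) / se
  df <- n - 1
  p <- switch(tail,
              two_sided = 2 * stats::pt(-abs(t), df),
              negative = stats::pt(t, df),
              positive = stats::pt(t, df, lower.tail = FALSE))
  ci <- m + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(estimate = m, t = t, df = df, p = p, tail = tail,
                 cohens_d = abs(m - mu0) / s, ci95 = ci, n = n),
            class = "sk_inference")
}

#' Two-group t-test (pooled or Welch)
#'
#' Independent-samples comparison of window amplitudes between conditions.
#' The pooled-variance variant (default) has `df = n1 + n2 - 2`; the effect
#' size is `|mean1 - mean2| / pooled sd`.
#'
#' @param group1,group2 numeric vectors, each `n >= 2`.
#' @param variant `"pooled"` or `"welch"`.
#' @param tail as in [one_sample_t()] (`"negative"` means group1 < group2).
#' @return An `sk_inference` (with `estimate` = mean difference).
#' @export
two_group_t <- function(group1, group2, variant = c("pooled", "welch"),
                        tail = c("two_sided", "negative", "positive")) {
  variant <- match.arg(variant)
  tail <- match.arg(tail)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  m <- mean(group1) - mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) stop("degenerate sample: zero pooled variance",
                       call. = FALSE)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    d <- abs(m) / sqrt(sp2)
  } else {
    if (v1 == 0 && v2 == 0) stop("degenerate sample: zero variance",
                                 call. = FALSE)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    d <- abs(m) / sqrt((v1 + v2) / 2)
  }
  t <- m / se
  p <- switch(tail,
              two_sided = 2 * stats::pt(-abs(t), df),
              negative = stats::pt(t, df),
              positive = stats::pt(t, df, lower.tail = FALSE))
  ci <- m + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(estimate = m, t = t, df = df, p = p, tail = tail,
                 cohens_d = d, ci95 = ci, n = c(n1, n2)),
            class = "sk_inference")
}

#' JZS default-prior Bayes factor for the one-sample design
#'
#' Bayes factor `BF10` computed from the t statistic and sample size by
#' numerical quadrature over a Cauchy prior on the standardized effect size
#' (scale 0.707 = 1/sqrt(2), the default of common Bayesian analysis
#' software). Under the alternative, the marginal likelihood integrates the
#' noncentral t density over the prior; one-sided variants restrict (and
#' renormalize) the prior to the requested half-line.
#'
#' @param t observed t statistic.
#' @param n sample size (one-sample design; `df = n - 1`).
#' @param scale Cauchy prior scale, > 0.
#' @param side `"two_sided"`, `"negative"`, or `"positive"`.
#' @return `bf10` (numeric, > 0).
#' @examples
#' jzs_bayes_factor(-2.4, 18, side = "negative")
#' @export
jzs_bayes_factor <- function(t, n, scale = 1 / sqrt(2),
                             side = c("two_sided", "negative", "positive")) {
  side <- match.arg(side)
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (scale <= 0) stop("prior scale must be > 0", call. = FALSE)
  df <- n - 1
  # integrate over the prior quantile u in (0,1): delta = scale*tan(pi(u-1/2))
  # maps the Cauchy prior to uniform, so the integrand is bounded and the
  # quadrature domain finite
  f <- function(u)
    suppressWarnings(
      stats::dt(t, df, ncp = scale * tan(pi * (u - 0.5)) * sqrt(n)))
  quad <- function(lo, hi) {
    r <- stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-14,
                          subdivisions = 500L, stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected") ||
        !is.finite(r$value) || r$value < 0)
      stop("numerical error: quadrature did not converge (", r$message, ")",
           call. = FALSE)
    r$value
  }
  m1 <- switch(side,
               two_sided = quad(0, 1),
               negative = 2 * quad(0, 0.5),
               positive = 2 * quad(0.5, 1))
  m0 <- stats::dt(t, df)
  m1 / m0
}

#' One-way between-groups analysis of variance
#'
#' Standard between/within decomposition via [stats::aov()], used for the
#' hit-rate-by-session analysis.
#'
#' @param values numeric outcomes (e.g. hit rates in percent).
#' @param groups group labels (e.g. session), coerced to factor.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(groups) < 2)) stop("each group needs n >= 2",
                                      call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  tab <- summary(stats::aov(values ~ groups))[[1]]
  list(F = tab["groups", "F value"], df1 = tab["groups", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["groups", "Pr(>F)"])
}

#' Evidence label for a Bayes factor
#'
#' Categorizes `BF10` by the conventional cut points 1, 3, 20, 150:
#' below 1 the data favor the null; `[1, 3)` weak, `[3, 20)` positive,
#' `[20, 150)` strong, and at or above 150 very strong evidence for the
#' alternative.
#'
#' @param bf10 Bayes factor, > 0 (vectorized).
#' @return character vector of labels.
#' @examples
#' interpret_bf(c(0.21, 2.77, 5.3, 170))
#' @export
interpret_bf <- function(bf10) {
  if (any(!is.finite(bf10) & !is.infinite(bf10)) || any(bf10 <= 0))
    stop("bf10 must be > 0", call. = FALSE)
  cut_labels <- c("favors null", "weak", "positive", "strong", "very strong")
  idx <- findInterval(bf10, c(1, 3, 20, 150)) + 1L
  cut_labels[idx]
}

#' Combined inference for one window amplitude sample
#'
#' Convenience wrapper assembling the full inference row used in the results
#' table: one-sample t (directional by default, negative), two-sided 95
#' percent CI, Cohen's d, JZS Bayes factor on the matching side, and its
#' evidence label.
#'
#' @param values per-participant window mean amplitudes (microvolts).
#' @param tail test tail; the Bayes factor side follows it.
#' @param scale Cauchy prior scale.
#' @return An `sk_inference` with `bf10` and `evidence_label` fields.
#' @export
window_inference <- function(values, tail = "negative", scale = 1 / sqrt(2)) {
  res <- one_sample_t(values, mu0 = 0, tail = tail)
  res$bf10 <- jzs_bayes_factor(res$t, res$n, scale = scale, side = tail)
  res$evidence_label <- interpret_bf(res$bf10)
  res
}

#' @export
print.sk_inference <- function(x, digits = 3, ...) {
  cat(sprintf("t(%s) = %s, p = %s (%s), d = %s, CI95 [%s, %s]\n",
              format(x$df, digits = digits), format(x$t, digits = digits),
              format.pval(x$p, digits = digits), x$tail,
              format(x$cohens_d, digits = digits),
              format(x$ci95[1], digits = digits),
              format(x$ci95[2], digits = digits)))
  if (!is.null(x$bf10))
    cat(sprintf("BF10 = %s (%s)\n", format(x$bf10, digits = digits),
                x$evidence_label))
  invisible(x)
}
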