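# Self-contained statistical primitives used throughout the pipeline:
# paired/one-sample t-tests with Cohen's d, JZS (Cauchy-prior) Bayes factors,
# and noncentral-t power for paired designs.

new_stat_result <- function(name, n, t, df, p, tail, cohen_d,
                            bf01 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                            note = NA_character_) {
  tibble(
    statistic = name, n = as.integer(n), t = t, df = as.integer(df), p = p,
    tail = tail, cohen_d = cohen_d, bf01 = bf01,
    ci_low = ci_low, ci_high = ci_high, note = note
  )
}

t_from_diffs <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  se <- s / sqrt(n)
  list(n = n, mean = m, sd = s, se = se,
       t = if (s == 0) { if (m == 0) 0 else sign(m) * Inf } else m / se)
}

p_from_t <- function(t, df, tail) {
  switch(tail,
    two.sided = 2 * pt(-abs(t), df),
    greater   = pt(t, df, lower.tail = FALSE),
    less      = pt(t, df)
  )
}

#' One-sample t-test against a fixed mean
#'
#' Closed-form one-sample t-test with Cohen's d (`mean(x - mu) / sd(x)`) and a
#' t-based 95% confidence interval for the mean. p-values are floored at the
#' smallest representable double rather than reported as exactly zero; a
#' zero-variance sample with nonzero mean is reported as the `t = +/-Inf`
#' limit and flagged in `note`.
#'
#' @param x numeric vector, length >= 2 after removing `NA`.
#' @param mu null-hypothesis mean.
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @param name label stored in the result row.
#' @return a one-row tibble (t, df, p, cohen_d, 95% CI for the mean).
#' @export
#' @examples
#' one_sample_t(c(.6, .7, .8), mu = .5)  # t = 3.464, df = 2
one_sample_t <- function(x, mu = 0, tail = c("two.sided", "greater", "less"),
                         name = "one_sample_t") {
  tail <- match.arg(tail)
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("one_sample_t() needs >= 2 non-missing values.",
                           class = "walkmem_config_error")
  st <- t_from_diffs(x - mu)
  note <- NA_character_
  p <- p_from_t(st$t, st$n - 1, tail)
  if (!is.finite(st$t)) {
    p <- .Machine$double.xmin
    note <- "zero-variance sample; p reported as limit"
  }
  p <- max(p, .Machine$double.xmin)
  ci <- mean_ci95(x)
  d <- if (st$sd > 0) st$mean / st$sd else if (st$mean == 0) 0 else NA_real_
  new_stat_result(name, st$n, st$t, st$n - 1, p, tail, cohen_d = d,
                  ci_low = ci[1], ci_high = ci[2], note = note)
}

#' Paired-samples t-test
#'
#' Equivalent to `one_sample_t(x - y, 0)`: the statistic is computed on the
#' within-pair differences and Cohen's d is `mean(diff) / sd(diff)` (the `dz`
#' convention for paired designs). Pairs with a missing value in either
#' member are dropped.
#'
#' @inheritParams one_sample_t
#' @param y second condition, same length as `x`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(1, 1, 1))  # diffs 0,1,2 -> t = sqrt(3), d = 1
paired_t <- function(x, y, tail = c("two.sided", "greater", "less"),
                     name = "paired_t") {
  tail <- match.arg(tail)
  if (length(x) != length(y)) abort("paired_t(): x and y must have equal length.",
                                    class = "walkmem_config_error")
  keep <- complete.cases(x, y)
  one_sample_t(x[keep] - y[keep], mu = 0, tail = tail, name = name)
}

#' Mean and t-based 95% confidence interval
#'
#' @param x numeric vector, length >= 2.
#' @return `c(low, high)`.
#' @export
mean_ci95 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("mean_ci95() needs >= 2 values.", class = "walkmem_config_error")
  half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean(x) - half, mean(x) + half)
}

# JZS marginal-likelihood integrand: the Cauchy(0, r) prior on the
# standardized effect is the scale mixture delta | g ~ N(0, g),
# g ~ InverseGamma(1/2, r^2/2), so the Bayes factor reduces to a
# one-dimensional integral over g (Zellner-Siow / JZS form).
jzs_bf10 <- function(t, n_eff, df, r_scale) {
  num_f <- function(g) {
    (1 + n_eff * g)^(-0.5) *
      (1 + t^2 / ((1 + n_eff * g) * df))^(-(df + 1) / 2) *
      r_scale / (sqrt(2 * pi) * g^1.5) * exp(-r_scale^2 / (2 * g))
  }
  num <- tryCatch(
    integrate(num_f, 0, Inf, rel.tol = 1e-10, subdivisions = 500L),
    error = function(e) abort(
      sprintf("JZS Bayes factor integration failed (t = %g, n_eff = %g): %s",
              t, n_eff, conditionMessage(e)),
      class = "walkmem_numeric_error")
  )
  if (num$message != "OK")
    abort(paste0("JZS Bayes factor integration did not converge: ", num$message),
          class = "walkmem_numeric_error")
  den <- (1 + t^2 / df)^(-(df + 1) / 2)
  num$value / den
}

#' JZS default-prior Bayes factor for the null (BF01)
#'
#' Bayes factor favouring the point null over a Cauchy(0, `r_scale`) prior on
#' the standardized effect size (the "default" JZS t-test prior, scale
#' sqrt(2)/2). One-sample/paired mode uses effective sample size `n1` and
#' `df = n1 - 1`; supplying `n2` switches to the independent-samples form with
#' effective sample size `n1*n2/(n1+n2)` and `df = n1 + n2 - 2`. The marginal
#' likelihood is evaluated by adaptive quadrature over the mixing variance.
#' BF01 is symmetric in the sign of `t`.
#'
#' @param t observed t statistic.
#' @param n1 sample size (first group, or the number of pairs).
#' @param n2 optional second group size (independent-samples mode).
#' @param r_scale Cauchy prior scale; default `sqrt(2)/2` ~ 0.707.
#' @return scalar BF01 (> 1 favours the null).
#' @export
#' @examples
#' jzs_bf01(0.72, 30)      # ~ 4.05: moderate evidence for the null
#' jzs_bf01(0.29, 9, 9)    # independent-samples mode, df = 16
jzs_bf01 <- function(t, n1, n2 = NULL, r_scale = sqrt(2) / 2) {
  stopifnot(is.numeric(t), length(t) == 1, is.finite(t))
  if (n1 < 2) abort("jzs_bf01() needs n1 >= 2.", class = "walkmem_config_error")
  if (is.null(n2)) {
    n_eff <- n1; df <- n1 - 1
  } else {
    if (n2 < 2) abort("jzs_bf01() needs n2 >= 2.", class = "walkmem_config_error")
    n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  1 / jzs_bf10(t, n_eff, df, r_scale)
}

#' Power of a paired-samples t-test
#'
#' Exact power from the noncentral t distribution: with `n` pairs and
#' standardized effect `dz = mean(diff)/sd(diff)`, the test statistic is
#' noncentral t with `df = n - 1` and noncentrality `dz * sqrt(n)`.
#'
#' @param n number of pairs (>= 2).
#' @param alpha significance level.
#' @param dz standardized paired effect size.
#' @param tail `"two.sided"` or `"greater"` (one-tailed in the direction of
#'   `dz`).
#' @return rejection probability in `[0, 1]`.
#' @export
#' @examples
#' power_paired_t(30, 0.05, 0.5)  # ~ 0.75
power_paired_t <- function(n, alpha, dz, tail = c("two.sided", "greater")) {
  tail <- match.arg(tail)
  if (n < 2 || alpha <= 0 || alpha >= 1)
    abort("power_paired_t() needs n >= 2 and 0 < alpha < 1.",
          class = "walkmem_config_error")
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (tail == "two.sided") {
    q <- qt(1 - alpha / 2, df)
    pt(q, df, ncp = ncp, lower.tail = FALSE) + pt(-q, df, ncp = ncp)
  } else {
    q <- qt(1 - alpha, df)
    pt(q, df, ncp = ncp, lower.tail = FALSE)
  }
}
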