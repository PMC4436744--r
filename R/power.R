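#' Exact power of the two-sample t-test
#'
#' Noncentral-t power for a two-sided pooled-variance two-sample t-test
#' with possibly unequal group sizes: with `df = n1 + n2 - 2` and
#' noncentrality `delta / (sd * sqrt(1/n1 + 1/n2))`, the power is
#' `P(|T| > t[1 - alpha/2, df])` under the noncentral distribution.
#'
#' @param delta True mean difference between groups (outcome units).
#' @param sd Common within-group standard deviation.
#' @param n1,n2 Group sizes (each at least 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1); equals `alpha` at `delta = 0`.
#' @export
power_two_sample_t <- function(delta, sd, n1, n2, alpha = 0.05) {
  if (sd <= 0) stop("sd must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- delta / (sd * sqrt(1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp) + stats::pt(-tcrit, df, ncp)
}

#' Simulation estimate of two-sample t-test power
#'
#' Monte-Carlo check of [power_two_sample_t()]: simulates normal two-sample
#' datasets and reports the rejection fraction of the pooled-variance
#' two-sided t-test together with its binomial Monte-Carlo standard error.
#'
#' @inheritParams power_two_sample_t
#' @param n_sim Number of simulated datasets (at least 100).
#' @param seed Integer seed.
#' @return Named vector `c(power, se)`.
#' @export
power_by_simulation <- function(delta, sd, n1, n2, alpha = 0.05,
                                n_sim = 10000, seed = 1L) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (sd <= 0) stop("sd must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  set.seed(seed)
  X1 <- matrix(stats::rnorm(n1 * n_sim, delta, sd), n1)
  X2 <- matrix(stats::rnorm(n2 * n_sim, 0, sd), n2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(sweep(X1, 2, m1)^2)
  ss2 <- colSums(sweep(X2, 2, m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  reject <- abs(tstat) > stats::qt(1 - alpha / 2, n1 + n2 - 2)
  pw <- mean(reject)
  c(power = pw, se = sqrt(pw * (1 - pw) / n_sim))
}
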