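#' Minimum per-group sample size for a two-sample t-test
#'
#' Smallest integer group size `n >= 2` whose two-sample t-test power reaches
#' `power_target`, computed from the noncentral t distribution: with effect
#' size `d = (mu1 - mu2) / sigma`, the test statistic under the alternative is
#' noncentral t with `df = 2n - 2` and noncentrality `d * sqrt(n / 2)`. The
#' default design (two-sided alpha, equal group sizes) reproduces the a priori
#' power analysis used to size animal cohorts: `d = 3.92`, `alpha = 0.05`,
#' power 0.95 gives `n = 4`.
#'
#' @param d Effect size (Cohen's d), > 0.
#' @param alpha Type-I error rate in (0, 1).
#' @param power_target Required power (1 - beta) in (0, 1).
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @param n_max Search cap; an unreachable target is an error.
#' @return Minimum per-group `n` (integer).
#' @examples
#' required_sample_size(d = 3.92)
#' @export
required_sample_size <- function(d, alpha = 0.05, power_target = 0.95,
                                 alternative = c("two.sided", "one.sided"),
                                 n_max = 1e6) {
  alternative <- match.arg(alternative)
  if (d <= 0) abort("`d` must be > 0.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (power_target <= 0 || power_target >= 1) abort("`power_target` must be in (0, 1).")
  n <- 2
  while (n <= n_max) {
    if (t_test_power(n, d, alpha, alternative) >= power_target) return(as.integer(n))
    n <- n + 1
  }
  abort(sprintf("Power %.3f unreachable within n <= %g.", power_target, n_max))
}

# Power of the two-sample t-test at per-group size n (noncentral t).
t_test_power <- function(n, d, alpha, alternative = "two.sided") {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (alternative == "two.sided") {
    tcrit <- qt(1 - alpha / 2, df)
    1 - pt(tcrit, df, ncp) + pt(-tcrit, df, ncp)
  } else {
    tcrit <- qt(1 - alpha, df)
    1 - pt(tcrit, df, ncp)
  }
}
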