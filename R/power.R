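#' Statistical power of an IVW estimate with a binary outcome
#'
#' Non-centrality approximation for a two-sided Wald test of the causal
#' log-odds ratio estimated by IVW from a case-control outcome GWAS.  With
#' `b = ln(OR)`, case fraction `K`, outcome sample size `n`, and instrument
#' variance explained `r2_xz`, the expected z-score is
#' `z = b * sqrt(n * r2_xz * K * (1 - K))` and
#' `power = 1 - pnorm(z_(1-alpha/2) - z) + pnorm(-z_(1-alpha/2) - z)`.
#' The computation is deterministic; at `OR = 1` the power equals `alpha`
#' exactly (the size of the test), and power is symmetric in `OR` and
#' `1/OR`.
#'
#' @param n Outcome-study sample size (cases + controls).
#' @param case_fraction Proportion of cases `K`, strictly in (0, 1).
#' @param r2_xz Variance of the exposure explained by the instruments,
#'   strictly in (0, 1).
#' @param odds_ratio Hypothesized odds ratio per unit exposure, > 0.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power as a fraction in (0, 1).
#' @examples
#' mr_power_binary(n = 361822, case_fraction = 682 / 361822,
#'                 r2_xz = 0.152, odds_ratio = 1.21)
#' @export
mr_power_binary <- function(n, case_fraction, r2_xz, odds_ratio, alpha = 0.05) {
  if (!is.numeric(n) || n <= 0) stop_input("n must be positive")
  if (!is.numeric(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    stop_input("case_fraction must be strictly inside (0, 1)")
  }
  if (!is.numeric(r2_xz) || r2_xz <= 0 || r2_xz >= 1) {
    stop_input("r2_xz must be strictly inside (0, 1)")
  }
  if (!is.numeric(odds_ratio) || odds_ratio <= 0) stop_input("odds_ratio must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  b <- log(odds_ratio)
  z <- b * sqrt(n * r2_xz * case_fraction * (1 - case_fraction))
  zq <- stats::qnorm(1 - alpha / 2)
  1 - stats::pnorm(zq - z) + stats::pnorm(-zq - z)
}

#' Outcome sample size needed for a target power
#'
#' Bisection helper inverting [mr_power_binary()] in `n`.
#'
#' @param target_power Desired power in (alpha, 1).
#' @param case_fraction,r2_xz,odds_ratio,alpha As in [mr_power_binary()].
#' @param n_max Upper bracket for the search.
#' @return Smallest sample size (rounded up) reaching the target power.
#' @export
mr_required_n_binary <- function(target_power, case_fraction, r2_xz, odds_ratio,
                                 alpha = 0.05, n_max = 1e9) {
  if (odds_ratio == 1) stop_input("power never exceeds alpha at odds_ratio = 1")
  f <- function(n) mr_power_binary(n, case_fraction, r2_xz, odds_ratio, alpha) -
    target_power
  if (f(n_max) < 0) stop_input("target power unreachable below n_max")
  ceiling(stats::uniroot(f, c(1, n_max), tol = 0.5)$root)
}
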