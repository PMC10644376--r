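# Accept either an mr_instruments object or a (harmonized) data frame and
# return the numeric vectors the estimators work on.
instrument_data <- function(x) {
  pairs <- if (inherits(x, "mr_instruments")) x$pairs else x
  if (!is.null(pairs$action_flag)) pairs <- harmonized_retained(pairs)
  if (nrow(pairs) == 0) stop_input("empty instrument set")
  list(snp_id = pairs$snp_id,
       beta_x = pairs$beta_x, se_x = pairs$se_x,
       beta_y = pairs$beta_y, se_y = pairs$se_y)
}

#' Wald ratio for a single variant
#'
#' Per-variant causal estimate: outcome effect divided by exposure effect,
#' with the first-order standard error `se_y / |beta_x|` (exposure-side
#' uncertainty ignored).
#'
#' @param beta_x,beta_y Exposure and outcome effects (vectorized).
#' @param se_y Outcome standard error.
#' @return List with components `ratio` and `se`.
#' @export
wald_ratio <- function(beta_x, beta_y, se_y) {
  if (any(beta_x == 0)) stop_input("degenerate instrument: beta_x = 0")
  list(ratio = beta_y / beta_x, se = se_y / abs(beta_x))
}

# Constructor for one estimator's result row (the Table-1 row type).
mr_estimate <- function(method, beta, se, pval, n_snps) {
  structure(list(method = method, n_snps = as.integer(n_snps),
                 beta = beta, se = se,
                 or_ = exp(beta),
                 ci_low = exp(beta - 1.96 * se),   # fixed normal multiplier
                 ci_high = exp(beta + 1.96 * se),
                 pval = pval),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p %.3g\n",
              x$method, x$n_snps, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snps, beta = x$beta, se = x$se,
             or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Meta-analysis of per-variant Wald ratios with first-order
#' inverse-variance weights `w_j = beta_x_j^2 / se_y_j^2`, equivalent to a
#' zero-intercept weighted regression of outcome on exposure effects with
#' weights `1 / se_y^2`. Under the multiplicative random-effects model
#' (default) the fixed-effects standard error is inflated by
#' `max(1, sqrt(Q / (J - 1)))`, with Q the Cochran heterogeneity statistic;
#' the point estimate is identical under both models. P-values are from the
#' normal distribution.
#'
#' @param x An [instrument_set()] or harmonized data frame.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` (method `"IVW"`).
#' @export
mr_ivw <- function(x, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  d <- instrument_data(x)
  J <- length(d$beta_x)
  wr <- wald_ratio(d$beta_x, d$beta_y, d$se_y)
  if (J == 1) {
    warning("single instrument: IVW degenerates to the Wald ratio")
    beta <- wr$ratio
    se <- wr$se
  } else {
    w <- d$beta_x^2 / d$se_y^2
    beta <- sum(w * wr$ratio) / sum(w)
    se <- sqrt(1 / sum(w))
    if (model == "multiplicative_random") {
      q <- sum(w * (wr$ratio - beta)^2)
      se <- se * max(1, sqrt(q / (J - 1)))
    }
  }
  mr_estimate("IVW", beta, se, 2 * stats::pnorm(-abs(beta / se)), J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights `1 / se_y^2`), after orienting every variant so
#' its exposure effect is non-negative. The slope is a pleiotropy-adjusted
#' causal estimate (valid when pleiotropy is independent of instrument
#' strength); the intercept estimates the average directional pleiotropic
#' effect per variant, and an intercept significantly away from zero signals
#' directional pleiotropy. Standard errors carry a multiplicative
#' overdispersion factor `max(1, sqrt(RSS_w / (J - 2)))`; p-values use the t
#' distribution with `J - 2` degrees of freedom.
#'
#' @param x An [instrument_set()] or harmonized data frame with at least 3
#'   variants.
#' @return List with components `estimate` (an `mr_estimate`, method
#'   `"MR_Egger"`) and `intercept` (list: `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(x) {
  d <- instrument_data(x)
  J <- length(d$beta_x)
  if (J < 3) stop_input("MR-Egger needs at least 3 instruments, got ", J)
  s <- ifelse(d$beta_x < 0, -1, 1)
  bx <- d$beta_x * s
  by <- d$beta_y * s
  w <- 1 / d$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  est <- stats::coef(fit)
  sm <- summary(fit)
  sigma <- sm$sigma                       # sqrt(weighted RSS / (J - 2))
  se_raw <- sm$coefficients[, "Std. Error"] / sigma
  se_adj <- se_raw * max(1, sigma)
  pvals <- 2 * stats::pt(-abs(est / se_adj), df = J - 2)
  list(estimate = mr_estimate("MR_Egger", est[["bx"]], se_adj[["bx"]],
                              pvals[["bx"]], J),
       intercept = list(intercept = est[["(Intercept)"]],
                        se = se_adj[["(Intercept)"]],
                        pval = pvals[["(Intercept)"]]))
}

# Weighted median of `values` with weights `w`: interpolate the sorted values
# at cumulative weight 1/2 (cumulative weight of value j taken at the centre
# of its mass, s_j = sum_{k<=j} w_k - w_j / 2).
weighted_median_point <- function(values, w) {
  ord <- order(values)
  values <- values[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, values, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Median of the per-variant Wald ratios under normalized inverse-variance
#' weights; consistent when at least half of the total weight comes from
#' valid instruments, hence robust to a minority of pleiotropic variants.
#' The point estimate is deterministic; the standard error comes from a
#' parametric bootstrap (exposure and outcome effects resampled from normal
#' distributions with their standard errors) and therefore requires a seed.
#'
#' @param x An [instrument_set()] or harmonized data frame with at least 3
#'   variants.
#' @param n_boot Bootstrap replicates for the standard error, default 1000.
#' @param seed Integer seed for the bootstrap (required).
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed) {
  if (missing(seed)) stop_config("mr_weighted_median requires a seed for the bootstrap")
  d <- instrument_data(x)
  J <- length(d$beta_x)
  if (J < 3) stop_input("weighted median needs at least 3 instruments, got ", J)
  # canonical order and orientation (beta_x >= 0) so the estimate and its
  # bootstrap SE are invariant to input row order and allele flips
  ord <- order(d$snp_id)
  s <- ifelse(d$beta_x[ord] < 0, -1, 1)
  bx <- d$beta_x[ord] * s; sx <- d$se_x[ord]
  by <- d$beta_y[ord] * s; sy <- d$se_y[ord]
  ratio <- by / bx
  w <- bx^2 / sy^2
  beta <- weighted_median_point(ratio, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxb <- stats::rnorm(J, bx, sx)
      byb <- stats::rnorm(J, by, sy)
      weighted_median_point(byb / bxb, bxb^2 / sy^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, 2 * stats::pnorm(-abs(beta / se)), J)
}

#' All three causal-effect estimates as one table
#'
#' Runs IVW (multiplicative random effects), weighted median, and MR-Egger on
#' the same instrument set and returns the combined results table with fixed
#' column order `method`, `nsnp`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#' `pval`.
#'
#' @param x An [instrument_set()] or harmonized data frame.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @param ivw_model Passed to [mr_ivw()].
#' @return Data frame with one row per method; the MR-Egger intercept is
#'   attached as `attr(x, "egger_intercept")`.
#' @export
mr_all_estimates <- function(x, n_boot = 1000, seed,
                             ivw_model = "multiplicative_random") {
  egger <- mr_egger(x)
  out <- rbind(as.data.frame(mr_ivw(x, model = ivw_model)),
               as.data.frame(mr_weighted_median(x, n_boot = n_boot, seed = seed)),
               as.data.frame(egger$estimate))
  attr(out, "egger_intercept") <- egger$intercept
  out
}
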