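#' Cochran's Q heterogeneity test and I-squared
#'
#' Measures dispersion of the per-variant Wald ratios around the
#' fixed-effects IVW estimate: `Q = sum_j w_j (r_j - beta_IVW)^2` with the
#' IVW weights, compared to a chi-square with `J - 1` degrees of freedom.
#' `I2 = max(0, (Q - df) / Q) * 100` quantifies the fraction of variation
#' attributable to heterogeneity, banded at the conventional cut-points:
#' below 25 low, 25 to 75 (inclusive) moderate, above 75 high.
#'
#' @param x An [instrument_set()] or harmonized data frame with at least 2
#'   variants.
#' @return Object of class `heterogeneity_result`: list with `q`, `df`,
#'   `pval`, `i2` (percentage), `band`.
#' @export
cochran_q <- function(x) {
  d <- instrument_data(x)
  J <- length(d$beta_x)
  if (J < 2) stop_input("heterogeneity test needs at least 2 instruments")
  r <- d$beta_y / d$beta_x
  w <- d$beta_x^2 / d$se_y^2
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  df <- J - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  band <- if (i2 < 25) "low" else if (i2 <= 75) "moderate" else "high"
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = i2, band = band),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d, p %.3g); I2 = %.2f%% (%s heterogeneity)\n",
              x$q, x$df, x$pval, x$i2, x$band))
  invisible(x)
}

# Leave-one-out IVW slopes via the sufficient statistics of the
# zero-intercept weighted fit: slope_{-j} = (Sxy - w_j x_j y_j) / (Sxx - w_j x_j^2)
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' Simulation-based pleiotropy and outlier test (MR-PRESSO style)
#'
#' Global test: the observed residual sum of squares, where each variant's
#' residual is taken against the IVW slope fitted *without* that variant
#' (weighted by `1 / se_y^2`), is compared with its null distribution
#' obtained by parametric simulation (outcome effects redrawn from
#' `N(slope_{-j} * beta_x_j, se_y_j)` and the statistic recomputed, including
#' the leave-one-out fits). Per-variant outlier p-values come from each
#' variant's simulated residual distribution, Bonferroni-corrected. When
#' outliers are found, the estimate is recomputed without them and a
#' distortion test compares the change against the distribution of changes
#' from removing equally many randomly chosen variants. Monte-Carlo p-values
#' use the `(1 + k) / (1 + n_sim)` estimator, so they are never exactly zero.
#'
#' @param x An [instrument_set()] or harmonized data frame with at least 4
#'   variants.
#' @param n_sim Number of parametric simulations, default 1000.
#' @param seed Integer seed (required; the test is seed-reproducible).
#' @param outlier_alpha Significance level for Bonferroni-corrected
#'   per-variant outlier calls, default 0.05.
#' @return Object of class `presso_result`: `global_rss`, `global_pval`,
#'   `outlier_snps` (data frame: snp_id, pval, pval_bonf), and when outliers
#'   exist, `distortion_pval` and `corrected_estimate`.
#' @export
mr_presso <- function(x, n_sim = 1000, seed, outlier_alpha = 0.05) {
  if (missing(seed)) stop_config("mr_presso requires a seed")
  d <- instrument_data(x)
  J <- length(d$beta_x)
  if (J < 4) stop_input("MR-PRESSO needs at least 4 instruments, got ", J)
  ord <- order(d$snp_id)   # canonical order: seed-reproducible and
  bx <- d$beta_x[ord]      # invariant to input row order
  by <- d$beta_y[ord]
  sy <- d$se_y[ord]
  ids <- d$snp_id[ord]
  w <- 1 / sy^2

  slope_loo <- loo_slopes(bx, by, w)
  res_obs <- (by - slope_loo * bx)^2 * w
  rss_obs <- sum(res_obs)

  sim <- with_seed(seed, {
    # n_sim x J matrix of outcome effects drawn under the no-pleiotropy null
    ymat <- matrix(stats::rnorm(n_sim * J, mean = rep(slope_loo * bx, each = n_sim),
                                sd = rep(sy, each = n_sim)),
                   nrow = n_sim, ncol = J)
    sxx <- sum(w * bx^2)
    sxy_s <- ymat %*% (w * bx)                      # per-sim Sxy
    num <- sweep(sweep(ymat, 2, w * bx, `*`), 1, sxy_s, function(a, b) b - a)
    den <- rep(sxx - w * bx^2, each = n_sim)
    slope_s <- matrix(num / den, nrow = n_sim)
    res_s <- sweep((ymat - sweep(slope_s, 2, bx, `*`))^2, 2, w, `*`)
    list(res = res_s, rss = rowSums(res_s))
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  p_snp <- (1 + colSums(sim$res >= rep(res_obs, each = n_sim))) / (1 + n_sim)
  p_bonf <- pmin(1, p_snp * J)
  is_out <- p_bonf < outlier_alpha
  outlier_snps <- data.frame(snp_id = ids[is_out], pval = p_snp[is_out],
                             pval_bonf = p_bonf[is_out], stringsAsFactors = FALSE)

  result <- list(global_rss = rss_obs, global_pval = global_pval,
                 outlier_snps = outlier_snps,
                 distortion_pval = NULL, corrected_estimate = NULL)
  if (any(is_out) && sum(!is_out) >= 2) {
    keep <- data.frame(snp_id = ids[!is_out], beta_x = bx[!is_out],
                       se_x = d$se_x[ord][!is_out], beta_y = by[!is_out],
                       se_y = sy[!is_out], stringsAsFactors = FALSE)
    corrected <- mr_ivw(keep)
    full <- mr_ivw(data.frame(snp_id = ids, beta_x = bx, se_x = d$se_x[ord],
                              beta_y = by, se_y = sy, stringsAsFactors = FALSE))
    d_obs <- full$beta - corrected$beta
    n_out <- sum(is_out)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(J, n_out)
        wj <- bx[-drop_idx]^2 / sy[-drop_idx]^2
        full$beta - sum(wj * by[-drop_idx] / bx[-drop_idx]) / sum(wj)
      }, numeric(1))
    })
    result$distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
    result$corrected_estimate <- corrected
  }
  structure(result, class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("Pleiotropy residual test: RSS = %.4g, global p = %.3g\n",
              x$global_rss, x$global_pval))
  if (nrow(x$outlier_snps) == 0) {
    cat("  no outlier variants detected\n")
  } else {
    cat(sprintf("  %d outlier variant(s): %s (distortion p = %.3g)\n",
                nrow(x$outlier_snps), paste(x$outlier_snps$snp_id, collapse = ", "),
                x$distortion_pval))
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the random-effects IVW effect with each variant excluded in
#' turn; an exclusion that changes the sign of the estimate or moves its
#' p-value across 0.05 marks that variant as influential.
#'
#' @param x An [instrument_set()] or harmonized data frame with at least 2
#'   variants (with exactly 2, each row degenerates to the other variant's
#'   Wald ratio).
#' @return Data frame of class `leave_one_out`: one row per excluded variant
#'   plus an `(all)` row holding the full-set estimate; columns `excluded`,
#'   `nsnp`, `beta`, `se`, `pval`, `sign_change`, `crosses_alpha`.
#' @export
leave_one_out <- function(x) {
  d <- instrument_data(x)
  J <- length(d$beta_x)
  if (J < 2) stop_input("leave-one-out needs at least 2 instruments")
  if (J == 2) warning("leave-one-out with 2 instruments degenerates to single Wald ratios")
  pairs <- data.frame(snp_id = d$snp_id, beta_x = d$beta_x, se_x = d$se_x,
                      beta_y = d$beta_y, se_y = d$se_y, stringsAsFactors = FALSE)
  full <- mr_ivw(pairs)
  one <- function(j) {
    est <- suppressWarnings(mr_ivw(pairs[-j, , drop = FALSE]))
    data.frame(excluded = pairs$snp_id[j], nsnp = est$n_snps, beta = est$beta,
               se = est$se, pval = est$pval, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(J), one))
  rows <- rbind(rows, data.frame(excluded = "(all)", nsnp = full$n_snps,
                                 beta = full$beta, se = full$se,
                                 pval = full$pval, stringsAsFactors = FALSE))
  rows$sign_change <- sign(rows$beta) != sign(full$beta)
  rows$crosses_alpha <- (rows$pval < 0.05) != (full$pval < 0.05)
  class(rows) <- c("leave_one_out", "data.frame")
  rows
}

#' Funnel-plot data
#'
#' One row per variant with its Wald ratio and precision (inverse of the
#' Wald standard error). Asymmetry of precision against ratio suggests
#' directional pleiotropy; plotting is a thin layer over this table.
#'
#' @param x An [instrument_set()] or harmonized data frame.
#' @return Data frame with columns `snp_id`, `wald_ratio`, `precision`.
#' @export
funnel_data <- function(x) {
  d <- instrument_data(x)
  wr <- wald_ratio(d$beta_x, d$beta_y, d$se_y)
  data.frame(snp_id = d$snp_id, wald_ratio = wr$ratio,
             precision = 1 / wr$se, stringsAsFactors = FALSE)
}

#' Funnel plot
#'
#' @param x An [instrument_set()] or harmonized data frame.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_funnel <- function(x, ...) {
  fd <- funnel_data(x)
  est <- mr_ivw(x)
  graphics::plot(fd$wald_ratio, fd$precision, xlab = "Wald ratio",
                 ylab = "Precision (1/SE)", pch = 19, ...)
  graphics::abline(v = est$beta, lty = 2)
  invisible(fd)
}

#' Combined sensitivity diagnostics
#'
#' Heterogeneity, Egger intercept, outlier test, and leave-one-out flags in
#' one list, writable as a single JSON document.
#'
#' @param x An [instrument_set()] or harmonized data frame.
#' @param n_sim,seed Passed to [mr_presso()] (the outlier test is skipped,
#'   with a note, when fewer than 4 instruments are available).
#' @return List with elements `heterogeneity`, `egger_intercept`, `presso`,
#'   `leave_one_out_flags`.
#' @export
sensitivity_report <- function(x, n_sim = 1000, seed) {
  het <- cochran_q(x)
  egger <- mr_egger(x)
  J <- nrow(if (inherits(x, "mr_instruments")) x$pairs else x)
  presso <- if (J >= 4) mr_presso(x, n_sim = n_sim, seed = seed) else NULL
  loo <- leave_one_out(x)
  influential <- loo$excluded[loo$excluded != "(all)" &
                                (loo$sign_change | loo$crosses_alpha)]
  list(heterogeneity = het[c("q", "df", "pval", "i2", "band")],
       egger_intercept = egger$intercept,
       presso = if (is.null(presso)) list(note = "skipped: fewer than 4 instruments")
                else list(global_rss = presso$global_rss,
                          global_pval = presso$global_pval,
                          n_outliers = nrow(presso$outlier_snps),
                          outlier_snps = presso$outlier_snps$snp_id,
                          distortion_pval = presso$distortion_pval),
       leave_one_out_flags = as.character(influential))
}
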