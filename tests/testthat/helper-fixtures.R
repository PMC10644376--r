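# Shared fixture builders and independent oracles.

# A random harmonized instrument table (already oriented, all retained).
random_instruments <- function(J, seed) {
  with_seed_helper(seed, {
    data.frame(snp_id = sprintf("rs%04d", sample.int(9999, J)),
               effect_allele = sample(c("A", "G"), J, replace = TRUE),
               other_allele = "C",
               beta_x = stats::runif(J, 0.05, 0.5) * sample(c(-1, 1), J, TRUE),
               se_x = stats::runif(J, 0.005, 0.05),
               beta_y = stats::rnorm(J, 0, 0.1),
               se_y = stats::runif(J, 0.02, 0.2),
               stringsAsFactors = FALSE)
  })
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Simulate one study and harmonize it (no palindromic variants, so all
# instruments survive and the truth is recovered exactly in expectation).
sim_harmonized <- function(seed, true_beta = 0.19, n_snps = 77,
                           mode = "none", p_mean = 0, p_sd = 0,
                           inside = FALSE) {
  truth <- simulate_two_sample(sim_config(
    n_snps = n_snps, true_beta = true_beta, pleiotropy_mode = mode,
    pleiotropy_mean = p_mean, pleiotropy_sd = p_sd,
    inside_violation = inside, palindromic_fraction = 0, seed = seed))
  suppressMessages(harmonize(truth$exposure, truth$outcome))
}

# Independent oracle: zero-intercept weighted least squares via lm's QR path.
oracle_ivw_fixed <- function(pairs) {
  fit <- stats::lm(beta_y ~ 0 + beta_x, data = pairs, weights = 1 / pairs$se_y^2)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit))
  se_fixed <- unname(sm$coefficients[1, "Std. Error"] / sm$sigma)
  list(beta = beta, se = se_fixed)
}

# Independent oracle: weighted median by explicit bracketing interpolation.
oracle_weighted_median <- function(values, w) {
  ord <- order(values)
  v <- values[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(s)])
  hi <- which(s >= 0.5)[1]
  lo <- hi - 1
  v[lo] + (v[hi] - v[lo]) * (0.5 - s[lo]) / (s[hi] - s[lo])
}

# Independent oracle for clumping a block-diagonal fixture where every
# within-block pair is in LD (r2 >= threshold) and within the window:
# the answer is the minimum-p SNP of each block (ties: position, then ID).
oracle_clump_blocks <- function(records, block) {
  keep <- unlist(lapply(split(seq_len(nrow(records)), block), function(idx) {
    r <- records[idx, , drop = FALSE]
    idx[order(r$pval, r$pos, r$snp_id)[1]]
  }))
  sort(records$snp_id[keep])
}

# Exhaustive independent-subset search (small instances only): all subsets
# with no pair violating the r2/window rule; returns the maximum-cardinality
# subsets.
exhaustive_independent_subsets <- function(records, ld, r2_threshold, window_kb) {
  J <- nrow(records)
  stopifnot(J <= 14)
  idx_ld <- match(records$snp_id, ld$snp_ids)
  ok_pair <- function(i, j) {
    same_chr <- identical(records$chrom[i], records$chrom[j])
    in_window <- same_chr && abs(records$pos[i] - records$pos[j]) <= window_kb * 1000
    !in_window || ld$r2[idx_ld[i], idx_ld[j]] < r2_threshold
  }
  valid <- list()
  for (mask in seq_len(2^J) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(J) - 1)) > 0)
    good <- TRUE
    if (length(members) > 1) {
      for (a in seq_along(members)[-1]) {
        for (b in seq_len(a - 1)) {
          if (!ok_pair(members[a], members[b])) { good <- FALSE; break }
        }
        if (!good) break
      }
    }
    if (good) valid[[length(valid) + 1]] <- members
  }
  sizes <- lengths(valid)
  valid[sizes == max(sizes)]
}
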