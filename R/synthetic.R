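#' Configuration for the two-sample summary-statistics simulator
#'
#' Defaults mirror the study conditions of a well-powered autoimmune
#' case-control exposure GWAS feeding a biobank-scale outcome GWAS: 77
#' instruments, causal log-odds effect 0.19, exposure study of 58,284
#' individuals (14,361 cases), outcome study of 361,822 (682 cases), with
#' per-instrument strength calibrated so the simulated F spectrum has a
#' floor near 30 (the weakest variant passing genome-wide significance), a
#' mean near 116, and a tail reaching roughly 1500.
#'
#' The per-variant noncentrality is drawn as
#' `lambda = min(f_cap, f_floor * exp(Exp(f_rate)))`, giving
#' `E[lambda] = f_floor * f_rate / (f_rate - 1)` (about 116 at the
#' defaults); the true exposure effect is `b_j = ±sqrt(lambda_j) * se_x_j`.
#'
#' @param n_snps Number of instruments.
#' @param true_beta Causal effect of the exposure on the outcome (log-odds
#'   per unit exposure).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_fraction_exposure,case_fraction_outcome Case proportions.
#' @param eaf_range Effect-allele frequencies drawn uniformly on this range.
#' @param f_floor,f_rate,f_cap Instrument-strength distribution parameters
#'   (see above).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects),
#'   or `"directional"` (non-zero mean). `"none"` forces both pleiotropy
#'   parameters to 0; `"balanced"` forces the mean to 0.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-variant direct
#'   (pleiotropic) effect on the outcome, on the outcome log-odds scale.
#' @param inside_violation When `TRUE`, the deterministic component of the
#'   pleiotropic effect is proportional to instrument strength `|b_j|`
#'   (violating the independence of pleiotropy from strength that MR-Egger
#'   assumes); when `FALSE`, pleiotropy is drawn independently of strength.
#' @param palindromic_fraction Fraction of variants assigned strand-ambiguous
#'   (A/T or C/G) alleles, to exercise harmonization.
#' @param seed Integer seed (required; tables regenerate bit-identically).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 77, true_beta = 0.19,
                       n_exposure = 58284, n_outcome = 361822,
                       case_fraction_exposure = 14361 / 58284,
                       case_fraction_outcome = 682 / 361822,
                       eaf_range = c(0.05, 0.95),
                       f_floor = 30, f_rate = 1.35, f_cap = 1500,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       inside_violation = FALSE,
                       palindromic_fraction = 0.05, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop_config("sim_config requires a seed")
  if (n_snps < 1 || n_exposure <= 0 || n_outcome <= 0) {
    stop_input("counts and sample sizes must be positive")
  }
  for (k in c(case_fraction_exposure, case_fraction_outcome)) {
    if (k <= 0 || k >= 1) stop_input("case fractions must be strictly inside (0, 1)")
  }
  if (pleiotropy_mode == "none") {
    pleiotropy_mean <- 0; pleiotropy_sd <- 0
  }
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    stop_input("balanced pleiotropy requires pleiotropy_mean = 0")
  }
  structure(list(n_snps = as.integer(n_snps), true_beta = true_beta,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction_exposure = case_fraction_exposure,
                 case_fraction_outcome = case_fraction_outcome,
                 eaf_range = eaf_range, f_floor = f_floor, f_rate = f_rate,
                 f_cap = f_cap, pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
                 inside_violation = inside_violation,
                 palindromic_fraction = palindromic_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Standard error of a per-allele log-odds estimate from a case-control GWAS:
# 1 / sqrt(2 p (1-p) n K (1-K)).
case_control_se <- function(eaf, n, case_fraction) {
  1 / sqrt(2 * eaf * (1 - eaf) * n * case_fraction * (1 - case_fraction))
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates exposure and outcome summary tables directly at the summary
#' level: per-variant standard errors follow the case-control log-odds
#' approximation for the configured sample sizes and allele frequencies,
#' observed effects are normal draws around the truth, and exposure and
#' outcome draws are independent (non-overlapping samples). The outcome
#' truth is `true_beta * b_j` plus a per-variant pleiotropic effect
#' according to the configured regime. A configurable fraction of variants
#' receives palindromic alleles, and the outcome table's allele orientation
#' is randomly scrambled (swaps and strand complements), so harmonization is
#' exercised end to end.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulation_truth`: list with `config`,
#'   `true_effects` (data frame: snp_id, b_exposure, alpha_pleiotropy),
#'   `exposure` and `outcome` summary tables.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    J <- config$n_snps
    snp_id <- sprintf("rs%07d", sample.int(9999999, J))
    chrom <- as.character(rep_len(1:22, J))
    pos <- ave(seq_len(J), chrom, FUN = seq_along) * 2.5e7  # > clump window apart
    eaf <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
    se_x <- case_control_se(eaf, config$n_exposure, config$case_fraction_exposure)
    lambda <- pmin(config$f_cap, config$f_floor * exp(stats::rexp(J, config$f_rate)))
    b <- sample(c(-1, 1), J, replace = TRUE) * sqrt(lambda) * se_x
    beta_x <- stats::rnorm(J, b, se_x)

    # Direct (pleiotropic) effects are defined in the exposure-increasing
    # allele frame; sign(b) maps them back onto the arbitrary effect-allele
    # labels, so "directional" stays directional after harmonization.
    delta <- switch(config$pleiotropy_mode,
      none = rep(0, J),
      balanced = stats::rnorm(J, 0, config$pleiotropy_sd),
      directional = if (config$inside_violation) {
        config$pleiotropy_mean * abs(b) / mean(abs(b)) +
          stats::rnorm(J, 0, config$pleiotropy_sd)
      } else {
        stats::rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd)
      })
    alpha <- sign(b) * delta

    se_y <- case_control_se(eaf, config$n_outcome, config$case_fraction_outcome)
    beta_y <- stats::rnorm(J, config$true_beta * b + alpha, se_y)

    n_pal <- round(config$palindromic_fraction * J)
    pal <- seq_len(J) %in% sample.int(J, n_pal)
    alleles <- matrix("", J, 2)
    alleles[!pal, ] <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), sum(!pal), replace = TRUE), , drop = FALSE]
    alleles[pal, ] <- PALINDROMIC_PAIRS[
      sample.int(nrow(PALINDROMIC_PAIRS), sum(pal), replace = TRUE), , drop = FALSE]

    exposure <- data.frame(snp_id = snp_id, effect_allele = alleles[, 1],
                           other_allele = alleles[, 2],
                           beta = beta_x, se = se_x,
                           pval = 2 * stats::pnorm(-abs(beta_x / se_x)),
                           eaf = eaf, n = config$n_exposure,
                           chrom = chrom, pos = pos, stringsAsFactors = FALSE)

    outcome <- data.frame(snp_id = snp_id, effect_allele = alleles[, 1],
                          other_allele = alleles[, 2],
                          beta = beta_y, se = se_y,
                          pval = 2 * stats::pnorm(-abs(beta_y / se_y)),
                          eaf = eaf, n = config$n_outcome,
                          chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    # scramble outcome orientation: random allele swaps and strand flips
    swap <- stats::runif(J) < 0.5
    outcome[swap, ] <- swap_orientation(outcome[swap, , drop = FALSE])
    strand <- stats::runif(J) < 0.5
    outcome$effect_allele[strand] <- unname(ALLELE_COMPLEMENT[outcome$effect_allele[strand]])
    outcome$other_allele[strand] <- unname(ALLELE_COMPLEMENT[outcome$other_allele[strand]])

    structure(list(config = config,
                   true_effects = data.frame(snp_id = snp_id, b_exposure = b,
                                             alpha_pleiotropy = alpha,
                                             stringsAsFactors = FALSE),
                   exposure = exposure, outcome = outcome),
              class = "simulation_truth")
  })
}

#' Write simulated tables in the package's TSV dialect
#'
#' Emits `exposure.tsv`, `outcome.tsv`, and `config.yaml` under `dir`, in the
#' same dialect [read_summary_table()] reads.
#'
#' @param truth A `simulation_truth` from [simulate_two_sample()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_tables <- function(truth, dir) {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_table(truth$exposure, file.path(dir, "exposure.tsv"))
  write_summary_table(truth$outcome, file.path(dir, "outcome.tsv"))
  yaml::write_yaml(unclass(truth$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Block-diagonal LD fixture with a known clumping answer
#'
#' Builds an LD matrix of `n_blocks` blocks of `block_size` variants with
#' pairwise r-squared `within_r2` inside each block and 0 between blocks,
#' plus positions on one chromosome. Within a block, variants are spaced
#' `spacing_kb` apart, so the window rule can be exercised both inside and
#' beyond the clumping window.
#'
#' @param n_blocks,block_size Block structure.
#' @param within_r2 Within-block r-squared, in \[0, 1).
#' @param seed Integer seed (variant IDs are randomized).
#' @param spacing_kb Distance between adjacent variants within a block, in
#'   kb; blocks start 50,000 kb apart.
#' @return List with `ld` (an [ld_matrix()] carrying positions) and `block`
#'   (the block index of every variant, in `ld$snp_ids` order).
#' @export
make_block_ld_fixture <- function(n_blocks, block_size, within_r2, seed,
                                  spacing_kb = 500) {
  if (within_r2 < 0 || within_r2 >= 1) stop_input("within_r2 must be in [0, 1)")
  with_seed(seed, {
    J <- n_blocks * block_size
    ids <- sprintf("rs%07d", sample.int(9999999, J))
    block <- rep(seq_len(n_blocks), each = block_size)
    r2 <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
    diag(r2) <- 1
    pos <- (block - 1) * 5e7 + (ave(seq_len(J), block, FUN = seq_along) - 1) *
      spacing_kb * 1000
    list(ld = ld_matrix(r2, ids, chrom = rep("1", J), pos = pos), block = block)
  })
}
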