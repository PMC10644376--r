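#' Build a pipeline run configuration
#'
#' All thresholds default to the conventional values of a two-sample MR
#' analysis: genome-wide significance 5e-8 on both exposure and outcome
#' sides, LD clumping at r-squared 0.001 within 10,000 kb, weak-instrument
#' gate F > 10, palindrome ambiguity half-width 0.08.
#'
#' @param exposure_path,outcome_path Summary-statistic input files (ignored
#'   when `harmonized_path` is given).
#' @param harmonized_path Optional pre-harmonized instrument table; when set,
#'   the selection stages are skipped (`skip_selection` is implied) so a
#'   published instrument list can be analyzed directly.
#' @param exposure_column_map,outcome_column_map Column maps
#'   (see [summary_column_map()]).
#' @param ld_path,ld_format Optional LD matrix input for clumping; clumping
#'   is skipped, with a log note, when absent.
#' @param p_exposure,p_outcome,clump_r2,clump_window_kb,f_min,palindrome_eaf_window
#'   Selection thresholds.
#' @param ivw_model,n_boot,presso_n_sim Estimator settings.
#' @param n_exposure Exposure sample size for variance explained (taken from
#'   the data when present).
#' @param power Optional named list for the power stage:
#'   `n`, `case_fraction`, `r2_xz` (defaults to the instrument set's total
#'   variance explained when `NULL`), `odds_ratio` (defaults to the IVW OR),
#'   `alpha`.
#' @param seed Integer seed for every stochastic step (required).
#' @param output_dir Where result files are written; `NULL` disables writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(exposure_path = NULL, outcome_path = NULL,
                       harmonized_path = NULL,
                       exposure_column_map = summary_column_map(),
                       outcome_column_map = summary_column_map(),
                       ld_path = NULL, ld_format = "square",
                       p_exposure = 5e-8, p_outcome = 5e-8,
                       clump_r2 = 0.001, clump_window_kb = 10000,
                       f_min = 10, palindrome_eaf_window = 0.08,
                       ivw_model = "multiplicative_random",
                       n_boot = 1000, presso_n_sim = 1000,
                       n_exposure = NULL, power = NULL,
                       seed, output_dir = NULL) {
  if (missing(seed)) stop_config("run_config requires a seed")
  for (v in list(p_exposure, p_outcome)) {
    if (v <= 0 || v > 1) stop_config("p-value thresholds must be in (0, 1]")
  }
  if (clump_r2 <= 0 || clump_r2 > 1) stop_config("clump_r2 must be in (0, 1]")
  if (f_min < 0) stop_config("f_min must be non-negative")
  structure(list(exposure_path = exposure_path, outcome_path = outcome_path,
                 harmonized_path = harmonized_path,
                 exposure_column_map = exposure_column_map,
                 outcome_column_map = outcome_column_map,
                 ld_path = ld_path, ld_format = ld_format,
                 p_exposure = p_exposure, p_outcome = p_outcome,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 f_min = f_min, palindrome_eaf_window = palindrome_eaf_window,
                 ivw_model = ivw_model, n_boot = n_boot,
                 presso_n_sim = presso_n_sim, n_exposure = n_exposure,
                 power = power, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  for (m in c("exposure_column_map", "outcome_column_map")) {
    if (!is.null(vals[[m]])) vals[[m]] <- do.call(summary_column_map, vals[[m]])
  }
  do.call(run_config, vals)
}

fail_empty <- function(pairs, stage) {
  if (nrow(pairs) == 0) {
    stop(errorCondition(
      paste0("no instruments survived the ", stage, " stage"),
      class = c("twosmr_empty_instruments", "error"),
      stage = stage))
  }
  pairs
}

#' Run the full two-sample MR analysis
#'
#' Executes read, harmonization, instrument selection (exposure
#' significance, LD clumping, outcome-association exclusion, F gate),
#' estimation (IVW, weighted median, MR-Egger), sensitivity diagnostics
#' (heterogeneity, Egger intercept, outlier test, leave-one-out, funnel
#' data), and optionally power. When `harmonized_path` is configured, the
#' selection stages are skipped and the table is analyzed as-is.
#'
#' If an output directory is configured, writes `estimates.tsv` (the
#' results table), `instruments.tsv`, `diagnostics.json`,
#' `selection_log.json`, `leave_one_out.tsv`, `funnel.tsv`, and
#' `summary.txt`. P-values are reported unadjusted across the three
#' estimators (stated in the summary header).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list: `instruments`, `estimates`,
#'   `egger_intercept`, `sensitivity`, `power`, `selection_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- NULL

  if (!is.null(config$harmonized_path)) {
    harmonized <- read_harmonized_table(config$harmonized_path)
    pairs <- harmonized_retained(harmonized)
    log <- log_stage(log, "pre-harmonized input", nrow(harmonized), nrow(pairs),
                     "selection stages skipped")
    fail_empty(pairs, "pre-harmonized input")
  } else {
    if (is.null(config$exposure_path) || is.null(config$outcome_path)) {
      stop_config("exposure_path and outcome_path (or harmonized_path) required")
    }
    exposure <- read_summary_table(config$exposure_path,
                                   column_map = config$exposure_column_map)
    outcome <- read_summary_table(config$outcome_path,
                                  column_map = config$outcome_column_map)
    harmonized <- harmonize(exposure, outcome,
                            palindrome_eaf_window = config$palindrome_eaf_window)
    pairs <- harmonized_retained(harmonized)
    log <- log_stage(log, "harmonization", nrow(harmonized), nrow(pairs))
    fail_empty(pairs, "harmonization")

    n_in <- nrow(pairs)
    pairs <- filter_exposure_significant(pairs, config$p_exposure)
    log <- log_stage(log, sprintf("exposure significance (p < %g)", config$p_exposure),
                     n_in, nrow(pairs))
    fail_empty(pairs, "exposure significance")

    if (!is.null(config$ld_path)) {
      ld <- read_ld_matrix(config$ld_path, format = config$ld_format)
      n_in <- nrow(pairs)
      pairs <- ld_clump(pairs, ld, r2_threshold = config$clump_r2,
                        window_kb = config$clump_window_kb)
      log <- log_stage(log, "LD clumping", n_in, nrow(pairs))
      fail_empty(pairs, "LD clumping")
    } else {
      log <- log_stage(log, "LD clumping", nrow(pairs), nrow(pairs),
                       "skipped: no LD matrix supplied")
    }

    n_in <- nrow(pairs)
    pairs <- exclude_outcome_significant(pairs, config$p_outcome)
    log <- log_stage(log, sprintf("outcome exclusion (p < %g)", config$p_outcome),
                     n_in, nrow(pairs))
    fail_empty(pairs, "outcome exclusion")
  }

  instruments <- instrument_set(pairs, n_exposure = config$n_exposure,
                                f_min = config$f_min, selection_log = log)
  fail_empty(instruments$pairs, "F gate")

  estimates <- mr_all_estimates(instruments, n_boot = config$n_boot,
                                seed = config$seed, ivw_model = config$ivw_model)
  sens <- sensitivity_report(instruments, n_sim = config$presso_n_sim,
                             seed = config$seed)
  loo <- leave_one_out(instruments)
  fd <- funnel_data(instruments)

  power <- NULL
  if (!is.null(config$power)) {
    p <- config$power
    r2 <- p$r2_xz %||% (if (!is.null(instruments$r2_exposure))
      sum(instruments$r2_exposure) else NULL)
    or_hyp <- p$odds_ratio %||% estimates$or[estimates$method == "IVW"]
    if (is.null(r2)) {
      warning("power stage skipped: variance explained unknown (no exposure n)")
    } else {
      power <- list(n = p$n, case_fraction = p$case_fraction, r2_xz = r2,
                    odds_ratio = or_hyp, alpha = p$alpha %||% 0.05)
      power$power <- do.call(mr_power_binary, power)
    }
  }

  report <- list(instruments = instruments, estimates = estimates,
                 egger_intercept = attr(estimates, "egger_intercept"),
                 sensitivity = sens, leave_one_out = loo, funnel = fd,
                 power = power, selection_log = instruments$selection_log,
                 seed = config$seed)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  invisible(report)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$estimates, file.path(dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_instrument_set(report$instruments, file.path(dir, "instruments.tsv"),
                       log_path = file.path(dir, "selection_log.json"))
  utils::write.table(report$leave_one_out, file.path(dir, "leave_one_out.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$funnel, file.path(dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  diag <- report$sensitivity
  diag$power <- report$power
  diag$seed <- report$seed
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c("Two-sample MR run summary",
               "p-values are unadjusted across the three estimators.",
               sprintf("seed: %d", report$seed), ""), con)
  utils::capture.output(print(report$instruments), file = con, append = FALSE)
  utils::capture.output(print(report$estimates, row.names = FALSE), file = con)
  invisible(dir)
}
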