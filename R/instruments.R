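#' Construct an LD matrix object
#'
#' Pairwise squared-correlation (r-squared) matrix between variants, as
#' supplied from an external reference panel. The matrix must be symmetric
#' with a unit diagonal and entries in \[0, 1\].
#'
#' @param r2 Square numeric matrix of pairwise r-squared values.
#' @param snp_ids Character vector naming the rows/columns.
#' @param chrom,pos Optional per-SNP chromosome labels and base-pair
#'   positions (1-based), used by the clumping window rule.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids, chrom = NULL, pos = NULL) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stop_input("r2 must be square with one row per snp_id")
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop_input("r2 entries must be finite and in [0,1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-12) stop_input("r2 must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop_input("r2 diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 chrom = chrom, pos = pos),
            class = "ld_matrix")
}

#' Read an LD matrix from plain text
#'
#' Accepts either a square matrix with a header row of SNP IDs (and the same
#' IDs as the first column) or a long-format table with columns
#' `snp_a`, `snp_b`, `r2`.
#'
#' @param path Path to the file.
#' @param format `"square"` or `"long"`.
#' @param delimiter Field separator.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, format = c("square", "long"), delimiter = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config("LD file not found: ", path)
  if (format == "square") {
    tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                             check.names = FALSE, row.names = 1)
    ld_matrix(as.matrix(tab), snp_ids = colnames(tab))
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                             stringsAsFactors = FALSE)
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    ia <- match(tab$snp_a, ids); ib <- match(tab$snp_b, ids)
    m[cbind(ia, ib)] <- tab$r2
    m[cbind(ib, ia)] <- tab$r2
    diag(m) <- 1
    ld_matrix(m, snp_ids = ids)
  }
}

#' Filter exposure records at genome-wide significance
#'
#' Retains records whose exposure p-value is strictly below the threshold
#' (conventionally 5e-8).
#'
#' @param records Summary records or harmonized pairs; the exposure p-value
#'   column is `pval` or `pval_x`.
#' @param p_threshold Significance threshold, default `5e-8`.
#' @return The retained rows.
#' @export
filter_exposure_significant <- function(records, p_threshold = 5e-8) {
  p <- records$pval %||% records$pval_x
  if (is.null(p)) stop_input("no exposure p-value column (pval / pval_x)")
  keep <- !is.na(p) & p < p_threshold
  message(sprintf("significance filter (p < %g): %d -> %d", p_threshold,
                  nrow(records), sum(keep)))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude instruments associated with the outcome
#'
#' Removes harmonized pairs whose outcome p-value is below the threshold:
#' such variants may act on the outcome directly rather than through the
#' exposure.
#'
#' @param pairs Harmonized pairs with a `pval_y` column.
#' @param p_threshold Significance threshold, default `5e-8`.
#' @return The retained pairs; removed SNP IDs are reported via [message()].
#' @export
exclude_outcome_significant <- function(pairs, p_threshold = 5e-8) {
  if (is.null(pairs$pval_y)) stop_input("no outcome p-value column (pval_y)")
  drop <- !is.na(pairs$pval_y) & pairs$pval_y < p_threshold
  if (any(drop)) {
    message("outcome-association exclusion removed: ",
            paste(pairs$snp_id[drop], collapse = ", "))
  } else {
    message("outcome-association exclusion removed no SNPs")
  }
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Selects independent index variants: records are visited in order of
#' ascending p-value (ties broken by genomic position, then SNP ID) and a
#' record is kept iff its r-squared with every already-kept record on the same
#' chromosome within `window_kb` is below `r2_threshold`. Pairs on different
#' chromosomes, or further apart than the window, are always treated as
#' independent. Records absent from the LD matrix are dropped with a warning.
#'
#' @param records Data frame with `snp_id` and a p-value column (`pval` or
#'   `pval_x`); `chrom`/`pos` columns enable the window rule (taken from the
#'   LD object when absent).
#' @param ld An [ld_matrix()].
#' @param r2_threshold Maximum allowed r-squared between kept records,
#'   default 0.001.
#' @param window_kb Window size in kilobases, default 10000 (10 Mb);
#'   `|pos_i - pos_j| <= window_kb * 1000` means "within window".
#' @return The kept records, in the original row order.
#' @export
ld_clump <- function(records, ld, r2_threshold = 0.001, window_kb = 10000) {
  if (!inherits(ld, "ld_matrix")) stop_input("ld must be an ld_matrix object")
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    stop_config("r2_threshold must be in (0, 1]")
  }
  p <- records$pval %||% records$pval_x
  if (is.null(p)) stop_input("no p-value column (pval / pval_x)")

  in_ld <- records$snp_id %in% ld$snp_ids
  if (any(!in_ld)) {
    warning("dropping ", sum(!in_ld), " SNP(s) absent from the LD matrix: ",
            paste(utils::head(records$snp_id[!in_ld], 5), collapse = ", "))
  }
  rec <- records[in_ld, , drop = FALSE]
  p <- p[in_ld]
  if (nrow(rec) == 0) return(rec)

  idx_ld <- match(rec$snp_id, ld$snp_ids)
  chrom <- rec$chrom %||% (if (!is.null(ld$chrom)) ld$chrom[idx_ld] else rep("1", nrow(rec)))
  pos <- rec$pos %||% (if (!is.null(ld$pos)) ld$pos[idx_ld] else rep(NA_real_, nrow(rec)))

  ord <- order(p, pos, rec$snp_id)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (k in kept) {
      same_chr <- identical(chrom[i], chrom[k])
      in_window <- same_chr &&
        (is.na(pos[i]) || is.na(pos[k]) ||
           abs(pos[i] - pos[k]) <= window_kb * 1000)
      if (in_window && ld$r2[idx_ld[i], idx_ld[k]] >= r2_threshold) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) kept <- c(kept, i)
  }
  message(sprintf("LD clumping (r2 < %g, %g kb): %d -> %d", r2_threshold,
                  window_kb, nrow(records), length(kept)))
  out <- rec[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-variant F statistic
#'
#' Instrument-strength statistic `F = (beta / se)^2`, the square of the
#' association z-score. `F > 10` is the conventional weak-instrument gate.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), all strictly positive.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop_input("se must be positive")
  (beta / se)^2
}

#' Total variance explained by a set of independent instruments
#'
#' Per-variant variance explained is recovered from the F statistic as
#' `r2_j = F_j / (F_j + n - 2)`; the total over independent instruments is
#' the sum.
#'
#' @param f_stats Non-negative per-variant F statistics.
#' @param n Exposure-study sample size (> 2).
#' @return List with `per_snp` (vector) and `total` (fraction in \[0, 1)).
#' @export
variance_explained <- function(f_stats, n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 2) {
    stop_input("n must be a single sample size > 2")
  }
  if (any(!is.finite(f_stats)) || any(f_stats < 0)) {
    stop_input("F statistics must be non-negative")
  }
  per_snp <- f_stats / (f_stats + n - 2)
  list(per_snp = per_snp, total = sum(per_snp))
}

#' Assemble an instrument set
#'
#' Bundles retained harmonized pairs with per-variant F statistics and (when
#' the exposure sample size is known) per-variant variance explained, and
#' applies the weak-instrument gate `F > f_min`. This is the unit every
#' estimator consumes.
#'
#' @param pairs Harmonized pairs (dropped rows are removed automatically).
#' @param n_exposure Exposure-study sample size; taken from an `n_x` column
#'   when `NULL`. Variance explained is left `NULL` if unknown.
#' @param f_min Weak-instrument threshold, default 10; variants with
#'   `F <= f_min` are removed.
#' @param selection_log Optional log (from earlier stages) to extend.
#' @return An object of class `mr_instruments`: list with elements `pairs`,
#'   `f_stats`, `r2_exposure`, `n_exposure`, `selection_log`.
#' @export
instrument_set <- function(pairs, n_exposure = NULL, f_min = 10,
                           selection_log = NULL) {
  if (!is.null(pairs$action_flag)) pairs <- harmonized_retained(pairs)
  n_in <- nrow(pairs)
  f <- f_statistic(pairs$beta_x, pairs$se_x)
  keep <- f > f_min
  if (any(!keep)) {
    message("F gate removed: ", paste(pairs$snp_id[!keep], collapse = ", "))
  }
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  f <- f[keep]
  selection_log <- log_stage(selection_log, sprintf("F gate (F > %g)", f_min),
                             n_in, nrow(pairs))
  n_exposure <- n_exposure %||% (if (!is.null(pairs$n_x)) max(pairs$n_x) else NULL)
  r2 <- if (!is.null(n_exposure)) variance_explained(f, n_exposure)$per_snp else NULL
  structure(list(pairs = pairs, f_stats = f, r2_exposure = r2,
                 n_exposure = n_exposure, selection_log = selection_log),
            class = "mr_instruments")
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat(sprintf("Instrument set: %d variants\n", nrow(x$pairs)))
  if (length(x$f_stats) > 0) {
    cat(sprintf("  F statistics: min %.1f, mean %.1f, max %.1f\n",
                min(x$f_stats), mean(x$f_stats), max(x$f_stats)))
  }
  if (!is.null(x$r2_exposure)) {
    cat(sprintf("  variance explained (n = %d): %.3f\n",
                as.integer(x$n_exposure), sum(x$r2_exposure)))
  }
  if (!is.null(x$selection_log)) {
    cat("  selection log:\n")
    for (i in seq_len(nrow(x$selection_log))) {
      cat(sprintf("    %-28s %5d -> %5d\n", x$selection_log$stage[i],
                  x$selection_log$n_in[i], x$selection_log$n_out[i]))
    }
  }
  invisible(x)
}

#' Export an instrument set as TSV
#'
#' Mirrors the harmonized-table layout with `f_stat` and `r2_exposure`
#' columns appended; the selection log can be written alongside as JSON.
#'
#' @param instruments An `mr_instruments` object.
#' @param path Output TSV path.
#' @param log_path Optional path for the selection log (JSON).
#' @export
write_instrument_set <- function(instruments, path, log_path = NULL) {
  tab <- instruments$pairs
  tab$f_stat <- instruments$f_stats
  if (!is.null(instruments$r2_exposure)) tab$r2_exposure <- instruments$r2_exposure
  write_harmonized_table(tab, path)
  if (!is.null(log_path) && !is.null(instruments$selection_log)) {
    jsonlite::write_json(instruments$selection_log, log_path,
                         dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
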