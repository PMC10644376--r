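#' Default column map for GWAS summary-statistic tables
#'
#' Maps the internal field names to the column headers expected in an input
#' file. Override any entry to match your file's dialect; set an optional
#' entry to `NULL` if the column is absent.
#'
#' @param snp_id,effect_allele,other_allele,beta,se,pval Required columns.
#' @param eaf,n,chrom,pos Optional columns (`NULL` when absent from the file).
#' @return Named list suitable for the `column_map` argument of
#'   [read_summary_table()].
#' @export
summary_column_map <- function(snp_id = "SNP", effect_allele = "EA",
                               other_allele = "OA", beta = "BETA", se = "SE",
                               pval = "P", eaf = "EAF", n = "N",
                               chrom = "CHR", pos = "POS") {
  list(snp_id = snp_id, effect_allele = effect_allele, other_allele = other_allele,
       beta = beta, se = se, pval = pval, eaf = eaf, n = n, chrom = chrom, pos = pos)
}

REQUIRED_FIELDS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
OPTIONAL_FIELDS <- c("eaf", "n", "chrom", "pos")

#' Read and validate a GWAS summary-statistic table
#'
#' Reads a delimited text file (plain or gzip-compressed) of per-SNP
#' association statistics, binds columns through `column_map`, and validates
#' every row: alleles must be single bases in A/C/G/T and differ, `se > 0`,
#' `pval` in (0, 1], and `eaf` strictly inside (0, 1) when present. Rows that
#' fail validation are rejected, with per-row diagnostics naming the offending
#' field; counts of read and rejected rows are reported via [message()].
#'
#' @param path Path to a TSV/CSV file (``.gz`` accepted).
#' @param column_map Named list from [summary_column_map()].
#' @param delimiter Field separator, default tab.
#' @return A `data.frame` with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and any of `eaf`, `n`, `chrom`,
#'   `pos` present in the file. Rejected-row diagnostics are attached as
#'   `attr(x, "rejected")`.
#' @export
read_summary_table <- function(path, column_map = summary_column_map(),
                               delimiter = "\t") {
  if (!file.exists(path)) stop_config("input file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- unlist(column_map[REQUIRED_FIELDS], use.names = FALSE)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_config("mapped column(s) absent from header: ",
                paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(snp_id = as.character(raw[[column_map$snp_id]]),
                    effect_allele = toupper(as.character(raw[[column_map$effect_allele]])),
                    other_allele = toupper(as.character(raw[[column_map$other_allele]])),
                    stringsAsFactors = FALSE)
  for (f in c("beta", "se", "pval")) {
    out[[f]] <- suppressWarnings(as.numeric(raw[[column_map[[f]]]]))
  }
  for (f in OPTIONAL_FIELDS) {
    col <- column_map[[f]]
    if (!is.null(col) && col %in% names(raw)) {
      out[[f]] <- if (f == "chrom") as.character(raw[[col]]) else
        suppressWarnings(as.numeric(raw[[col]]))
    }
  }
  validated <- validate_summary_records(out)
  message(sprintf("read_summary_table: %d rows read, %d retained, %d rejected [%s]",
                  nrow(out), nrow(validated), nrow(out) - nrow(validated),
                  basename(path)))
  validated
}

#' Validate summary records against the field invariants
#'
#' @param records Data frame with the summary-statistic columns.
#' @return The retained rows; rejected-row diagnostics (row number, field,
#'   reason) attached as `attr(x, "rejected")`.
#' @export
validate_summary_records <- function(records) {
  bad_field <- character(nrow(records))
  flag <- function(cond, field) {
    cond[is.na(cond)] <- TRUE
    bad_field[cond & !nzchar(bad_field)] <<- field
  }
  flag(!(records$effect_allele %in% VALID_ALLELES), "effect_allele")
  flag(!(records$other_allele %in% VALID_ALLELES), "other_allele")
  flag(records$effect_allele == records$other_allele, "alleles")
  flag(!is.finite(records$beta), "beta")
  flag(!is.finite(records$se) | records$se <= 0, "se")
  flag(!is.finite(records$pval) | records$pval <= 0 | records$pval > 1, "pval")
  if (!is.null(records$eaf)) {
    e <- records$eaf
    flag(!is.na(e) & (e <= 0 | e >= 1), "eaf")  # NA eaf tolerated
  }
  if (!is.null(records$n)) {
    n <- records$n
    flag(!is.na(n) & n <= 0, "n")
  }
  keep <- !nzchar(bad_field)
  rejected <- data.frame(row = which(!keep),
                         snp_id = records$snp_id[!keep],
                         field = bad_field[!keep],
                         stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a summary-statistic table
#'
#' Inverse of [read_summary_table()]: emits the same dialect so that a
#' read-write-read round trip reproduces all retained records exactly.
#'
#' @param records Data frame of summary records.
#' @param path Output path.
#' @param column_map Column-name mapping (internal name -> header).
#' @param delimiter Field separator.
#' @export
write_summary_table <- function(records, path,
                                column_map = summary_column_map(),
                                delimiter = "\t") {
  out <- records[, intersect(c(REQUIRED_FIELDS, OPTIONAL_FIELDS), names(records)),
                 drop = FALSE]
  hdr <- vapply(names(out), function(f) column_map[[f]] %||% f, character(1))
  names(out) <- hdr
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A palindromic (strand-ambiguous) variant has alleles that are reverse
#' complements of each other, i.e. the pair \{A, T\} or \{C, G\}: the same two
#' letters are read on either strand, so strand orientation cannot be inferred
#' from the alleles alone.
#'
#' @param effect_allele,other_allele Character vectors of single bases.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  ok <- effect_allele %in% VALID_ALLELES & other_allele %in% VALID_ALLELES
  if (!all(ok)) {
    stop_input("allele outside {A,C,G,T}: ",
               paste(unique(c(effect_allele, other_allele)[
                 !c(effect_allele %in% VALID_ALLELES, other_allele %in% VALID_ALLELES)]),
                 collapse = ", "))
  }
  unname(ALLELE_COMPLEMENT[effect_allele] == other_allele)
}

#' Swap the allele orientation of summary records
#'
#' Re-expresses effects on the opposite allele: effect and other allele are
#' exchanged, `beta` is negated, and `eaf` becomes `1 - eaf`. Applying the
#' transform twice returns the original records (involution).
#'
#' @param records Data frame with allele, `beta` and optionally `eaf` columns.
#' @return The re-oriented records.
#' @export
swap_orientation <- function(records) {
  tmp <- records$effect_allele
  records$effect_allele <- records$other_allele
  records$other_allele <- tmp
  records$beta <- -records$beta
  if (!is.null(records$eaf)) records$eaf <- 1 - records$eaf
  records
}

# Classify how outcome alleles (b1/b2) relate to exposure alleles (a1/a2).
# Returns one of "same", "swap", "incompatible".  Strand complements count as
# the corresponding orientation.
match_orientation <- function(a1, a2, b1, b2) {
  c1 <- unname(ALLELE_COMPLEMENT[a1]); c2 <- unname(ALLELE_COMPLEMENT[a2])
  ifelse((b1 == a1 & b2 == a2) | (b1 == c1 & b2 == c2), "same",
    ifelse((b1 == a2 & b2 == a1) | (b1 == c2 & b2 == c1), "swap", "incompatible"))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects onto the exposure's effect allele for every SNP
#' present in both tables. Outcome records whose alleles match the exposure
#' orientation (directly or as strand complements) are kept unchanged; records
#' in the swapped orientation have `beta` negated and `eaf` reflected
#' (`outcome_flipped`). Palindromic variants cannot be oriented from alleles
#' alone: they are aligned by allele frequency when both frequencies clearly
#' depart from 0.5, and dropped (`dropped_palindromic`) when either frequency
#' is missing or within `palindrome_eaf_window` of 0.5. Allele sets that match
#' under neither identity, swap, strand complement, nor complement swap are
#' dropped as incompatible.
#'
#' @param exposure,outcome Summary-record data frames (see
#'   [read_summary_table()]), keyed by `snp_id`. Duplicate IDs within a table
#'   are an error, never silently deduplicated.
#' @param palindrome_eaf_window Half-width of the ambiguity window around an
#'   allele frequency of 0.5 (default 0.08, i.e. frequencies in \[0.42, 0.58\]
#'   are considered uninformative about strand).
#' @return A harmonized data frame with one row per shared SNP and columns
#'   `snp_id`, `effect_allele`, `other_allele`, `beta_x`, `se_x`, `pval_x`,
#'   `beta_y`, `se_y`, `pval_y`, `eaf_x`, `eaf_y`, `action_flag` (plus
#'   `chrom`/`pos`/`n_x`/`n_y` when available), sorted by `snp_id` so the
#'   result is independent of input row order. Dropped SNPs are retained in
#'   the table with their drop flag; use [harmonized_retained()] before
#'   estimation.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  for (nm in list(c("exposure", "outcome")[1], c("exposure", "outcome")[2])) {
    tab <- if (nm == "exposure") exposure else outcome
    dup <- unique(tab$snp_id[duplicated(tab$snp_id)])
    if (length(dup) > 0) {
      stop_input("duplicate snp_id in ", nm, " table: ",
                 paste(utils::head(dup, 5), collapse = ", "))
    }
  }
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  message(sprintf("harmonize: %d exposure x %d outcome SNPs, %d shared",
                  nrow(exposure), nrow(outcome), length(shared)))
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  eaf_x <- if (is.null(ex$eaf)) rep(NA_real_, nrow(ex)) else ex$eaf
  eaf_y <- if (is.null(ou$eaf)) rep(NA_real_, nrow(ou)) else ou$eaf
  beta_y <- ou$beta
  orient <- match_orientation(ex$effect_allele, ex$other_allele,
                              ou$effect_allele, ou$other_allele)
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  flag <- character(length(shared))

  ambiguous <- pal &
    (is.na(eaf_x) | is.na(eaf_y) |
       abs(eaf_x - 0.5) <= palindrome_eaf_window |
       abs(eaf_y - 0.5) <= palindrome_eaf_window)
  # Palindromic but frequency-resolvable: align by which side of 0.5 each
  # frequency falls on (orientation from alleles is meaningless here).
  pal_keep <- pal & !ambiguous & orient != "incompatible"
  pal_flip <- pal_keep & (sign(eaf_x - 0.5) != sign(eaf_y - 0.5))

  flag[orient == "same"] <- "unchanged"
  flag[orient == "swap"] <- "outcome_flipped"
  flag[orient == "incompatible"] <- "dropped_incompatible"
  flag[pal & ambiguous & orient != "incompatible"] <- "dropped_palindromic"
  flag[pal_keep] <- ifelse(pal_flip[pal_keep], "outcome_flipped", "unchanged")

  do_flip <- flag == "outcome_flipped"
  beta_y[do_flip] <- -beta_y[do_flip]
  eaf_y[do_flip] <- 1 - eaf_y[do_flip]

  out <- data.frame(snp_id = shared,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval,
                    beta_y = beta_y, se_y = ou$se, pval_y = ou$pval,
                    eaf_x = eaf_x, eaf_y = eaf_y,
                    action_flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(ex$chrom)) out$chrom <- ex$chrom
  if (!is.null(ex$pos)) out$pos <- ex$pos
  if (!is.null(ex$n)) out$n_x <- ex$n
  if (!is.null(ou$n)) out$n_y <- ou$n
  out <- out[order(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("harmonize: %d retained, %d dropped palindromic, %d dropped incompatible",
                  sum(flag %in% c("unchanged", "outcome_flipped")),
                  sum(flag == "dropped_palindromic"),
                  sum(flag == "dropped_incompatible")))
  out
}

#' Retained rows of a harmonized table
#'
#' Drops rows flagged `dropped_palindromic` or `dropped_incompatible`; dropped
#' pairs carry no estimator weight.
#'
#' @param harmonized Output of [harmonize()].
#' @return The retained rows.
#' @export
harmonized_retained <- function(harmonized) {
  out <- harmonized[harmonized$action_flag %in% c("unchanged", "outcome_flipped"), ,
                    drop = FALSE]
  rownames(out) <- NULL
  out
}

HARMONIZED_COLUMNS <- c("snp_id", "effect_allele", "other_allele",
                        "beta_x", "se_x", "pval_x", "beta_y", "se_y", "pval_y",
                        "eaf_x", "eaf_y", "action_flag")

#' Write a harmonized table as TSV
#'
#' Fixed column order: snp_id, effect_allele, other_allele, beta_x, se_x,
#' pval_x, beta_y, se_y, pval_y, eaf_x, eaf_y, action_flag; any extra columns
#' (positions, sample sizes, F statistics) follow.
#'
#' @param harmonized Output of [harmonize()].
#' @param path Output path.
#' @export
write_harmonized_table <- function(harmonized, path) {
  extra <- setdiff(names(harmonized), HARMONIZED_COLUMNS)
  cols <- c(intersect(HARMONIZED_COLUMNS, names(harmonized)), extra)
  utils::write.table(harmonized[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a harmonized table written by [write_harmonized_table()]
#'
#' Entry point for pre-harmonized instrument tables (e.g. a published
#' supplementary instrument list), bypassing the raw-GWAS selection stages.
#'
#' @param path Path to a TSV with at least the columns `snp_id`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`; missing `action_flag` is assumed `unchanged`.
#' @param delimiter Field separator.
#' @return Harmonized data frame.
#' @export
read_harmonized_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_config("input file not found: ", path)
  out <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols) > 0) {
    stop_config("harmonized table lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  if (is.null(out$action_flag)) out$action_flag <- "unchanged"
  bad <- !is.finite(out$se_x) | out$se_x <= 0 | !is.finite(out$se_y) | out$se_y <= 0
  bad <- bad & out$action_flag %in% c("unchanged", "outcome_flipped")
  if (any(bad)) {
    stop_input("non-positive standard error for retained pair(s): ",
               paste(utils::head(out$snp_id[bad], 5), collapse = ", "))
  }
  out
}
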