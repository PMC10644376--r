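#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer (reproducibility contract)", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("twosmr_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("twosmr_input_error", "error")))
}

# Append a row to a selection log (stage name, input count, output count).
log_stage <- function(log, stage, n_in, n_out, note = "") {
  row <- data.frame(stage = stage, n_in = n_in, n_out = n_out, note = note,
                    stringsAsFactors = FALSE)
  if (is.null(log)) row else rbind(log, row)
}

VALID_ALLELES <- c("A", "C", "G", "T")
ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")
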