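test_that("reading binds mapped columns and validates rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP\tN\tEAF",
               "rs1\tA\tG\t0.10\t0.02\t1e-9\t1000\t0.30",
               "rs2\tC\tT\t-0.05\t0.01\t0.5\t1000\t0.70",
               "rs3\tG\tA\t0.20\t0.04\t2e-8\t1000\t0.10"), path)
  tab <- suppressMessages(read_summary_table(path))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(tab$beta, c(0.10, -0.05, 0.20))
  expect_equal(tab$eaf, c(0.30, 0.70, 0.10))
  expect_equal(nrow(attr(tab, "rejected")), 0)
})

test_that("invalid rows are rejected with a field diagnostic", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
               "rs1\tA\tG\t0.1\t0\t1e-9",     # se = 0
               "rs2\tA\tA\t0.1\t0.02\t1e-9",  # identical alleles
               "rs3\tA\tG\t0.1\t0.02\t1.5",   # pval > 1
               "rs4\tA\tG\tx\t0.02\t0.5",     # unparseable beta
               "rs5\tT\tC\t0.1\t0.02\t0.5"), path)
  tab <- suppressMessages(read_summary_table(path))
  expect_equal(tab$snp_id, "rs5")
  rej <- attr(tab, "rejected")
  expect_equal(rej$field, c("se", "alleles", "pval", "beta"))
  expect_equal(rej$row, 1:4)
})

test_that("a missing mapped column is a configuration error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE", "rs1\tA\tG\t0.1\t0.02"), path)
  expect_error(read_summary_table(path), class = "twosmr_config_error")
})

test_that("read-write-read round trip reproduces retained records exactly", {
  truth <- simulate_two_sample(sim_config(n_snps = 25, seed = 301))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(truth$exposure, path)
  back <- suppressMessages(read_summary_table(path))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(back, path2)
  back2 <- suppressMessages(read_summary_table(path2))
  attr(back, "rejected") <- attr(back2, "rejected") <- NULL
  expect_identical(back, back2)
  expect_equal(back$beta, truth$exposure$beta, tolerance = 1e-12)
})

test_that("gzip-compressed input is read transparently", {
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(path, "w")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP", "rs1\tA\tG\t0.1\t0.02\t1e-9"), con)
  close(con)
  tab <- suppressMessages(read_summary_table(path))
  expect_equal(tab$snp_id, "rs1")
})

test_that("palindromic classification follows the complement rule", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
  expect_error(is_palindromic("A", "N"), class = "twosmr_input_error")
})

make_pair_tables <- function(out_ea, out_oa, out_beta = 0.05,
                             eaf_x = 0.3, eaf_y = 0.3) {
  list(exposure = data.frame(snp_id = "rs1", effect_allele = "A",
                             other_allele = "G", beta = 0.1, se = 0.02,
                             pval = 1e-9, eaf = eaf_x, stringsAsFactors = FALSE),
       outcome = data.frame(snp_id = "rs1", effect_allele = out_ea,
                            other_allele = out_oa, beta = out_beta, se = 0.03,
                            pval = 0.2, eaf = eaf_y, stringsAsFactors = FALSE))
}

test_that("harmonization aligns identity, swap, and strand-complement orientations", {
  cases <- list(
    list(ea = "A", oa = "G", flag = "unchanged", beta_y = 0.05),
    list(ea = "G", oa = "A", flag = "outcome_flipped", beta_y = -0.05),
    list(ea = "T", oa = "C", flag = "unchanged", beta_y = 0.05),   # strand complement
    list(ea = "C", oa = "T", flag = "outcome_flipped", beta_y = -0.05),
    list(ea = "A", oa = "C", flag = "dropped_incompatible", beta_y = NA))
  for (cs in cases) {
    tabs <- make_pair_tables(cs$ea, cs$oa)
    h <- suppressMessages(harmonize(tabs$exposure, tabs$outcome))
    expect_equal(h$action_flag, cs$flag)
    if (!is.na(cs$beta_y)) expect_equal(h$beta_y, cs$beta_y)
  }
})

test_that("palindromic variants are dropped exactly when frequency is ambiguous", {
  # enumerate the frequency rule over a grid of eaf values
  for (eaf in seq(0.05, 0.95, by = 0.01)) {
    expo <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "T",
                       beta = 0.1, se = 0.02, pval = 1e-9, eaf = eaf,
                       stringsAsFactors = FALSE)
    outc <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "T",
                       beta = 0.05, se = 0.03, pval = 0.2, eaf = eaf,
                       stringsAsFactors = FALSE)
    h <- suppressMessages(harmonize(expo, outc))
    if (abs(eaf - 0.5) <= 0.08) {
      expect_equal(h$action_flag, "dropped_palindromic", info = paste("eaf", eaf))
    } else {
      expect_equal(h$action_flag, "unchanged", info = paste("eaf", eaf))
    }
  }
  # missing frequency is always ambiguous
  tabs <- make_pair_tables("A", "T", eaf_x = NA)
  tabs$exposure$other_allele <- "T"
  h <- suppressMessages(harmonize(tabs$exposure, tabs$outcome))
  expect_equal(h$action_flag, "dropped_palindromic")
})

test_that("frequency-resolvable palindromic variants are aligned by frequency", {
  # frequencies on the same side of 0.5: keep orientation
  expo <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "T",
                     beta = 0.1, se = 0.02, pval = 1e-9, eaf = 0.2,
                     stringsAsFactors = FALSE)
  outc <- expo; outc$beta <- 0.05; outc$se <- 0.03; outc$pval <- 0.2; outc$eaf <- 0.25
  h <- suppressMessages(harmonize(expo, outc))
  expect_equal(h$action_flag, "unchanged")
  expect_equal(h$beta_y, 0.05)
  # opposite sides: flip
  outc$eaf <- 0.75
  h <- suppressMessages(harmonize(expo, outc))
  expect_equal(h$action_flag, "outcome_flipped")
  expect_equal(h$beta_y, -0.05)
  expect_equal(h$eaf_y, 0.25)
})

test_that("orientation swap is an involution", {
  truth <- simulate_two_sample(sim_config(n_snps = 40, seed = 302))
  rec <- truth$exposure
  expect_equal(swap_orientation(swap_orientation(rec)), rec)
})

test_that("harmonization output is independent of input row order", {
  truth <- simulate_two_sample(sim_config(n_snps = 50, seed = 303))
  h1 <- suppressMessages(harmonize(truth$exposure, truth$outcome))
  shuf <- with_seed_helper(1, {
    list(e = truth$exposure[sample.int(50), ], o = truth$outcome[sample.int(50), ])
  })
  h2 <- suppressMessages(harmonize(shuf$e, shuf$o))
  rownames(h2) <- NULL
  expect_identical(h1, h2)
})

test_that("no retained pair is palindromic with frequency in the ambiguity window", {
  for (seed in 1:10) {
    truth <- simulate_two_sample(sim_config(n_snps = 60, seed = seed,
                                            palindromic_fraction = 0.4))
    h <- suppressMessages(harmonize(truth$exposure, truth$outcome))
    kept <- harmonized_retained(h)
    pal <- is_palindromic(kept$effect_allele, kept$other_allele)
    in_window <- abs(kept$eaf_x - 0.5) <= 0.08 | abs(kept$eaf_y - 0.5) <= 0.08
    expect_false(any(pal & in_window))
  }
})

test_that("duplicate variant IDs are a hard input error", {
  tabs <- make_pair_tables("A", "G")
  dup <- rbind(tabs$exposure, tabs$exposure)
  expect_error(harmonize(dup, tabs$outcome), class = "twosmr_input_error")
  expect_error(suppressMessages(harmonize(tabs$exposure, rbind(tabs$outcome, tabs$outcome))),
               class = "twosmr_input_error")
})

test_that("harmonized tables round trip through TSV", {
  truth <- simulate_two_sample(sim_config(n_snps = 30, seed = 304))
  h <- suppressMessages(harmonize(truth$exposure, truth$outcome))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized_table(h, path)
  back <- read_harmonized_table(path)
  expect_equal(back$snp_id, h$snp_id)
  expect_equal(back$beta_y, h$beta_y, tolerance = 1e-12)
  expect_equal(back$action_flag, h$action_flag)
})
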