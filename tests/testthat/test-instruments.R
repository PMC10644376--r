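test_that("significance filter uses a strict inequality and logs counts", {
  rec <- data.frame(snp_id = c("a", "b", "c"), pval = c(4e-8, 5e-8, 1e-9))
  kept <- suppressMessages(filter_exposure_significant(rec))
  expect_equal(kept$snp_id, c("a", "c"))
  expect_equal(nrow(suppressMessages(filter_exposure_significant(rec[0, ]))), 0)
})

test_that("significance filter count matches direct enumeration on simulated p-values", {
  p <- with_seed_helper(11, 10^-stats::runif(100, 4, 12))
  rec <- data.frame(snp_id = sprintf("rs%d", 1:100), pval = p)
  kept <- suppressMessages(filter_exposure_significant(rec))
  expect_equal(nrow(kept), sum(p < 5e-8))
  expect_gt(nrow(kept), 0)
})

test_that("outcome-association exclusion removes outcome-significant pairs", {
  pairs <- data.frame(snp_id = c("a", "b"), pval_y = c(1e-9, 0.3))
  expect_equal(suppressMessages(exclude_outcome_significant(pairs))$snp_id, "b")
  p <- with_seed_helper(12, c(10^-stats::runif(48, 0, 6), 1e-10, 1e-9))
  pairs <- data.frame(snp_id = sprintf("rs%d", 1:50), pval_y = p)
  expect_equal(nrow(suppressMessages(exclude_outcome_significant(pairs))), 48)
})

test_that("the F statistic is (beta/se)^2, scale-invariant, and matches the significance gate", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_error(f_statistic(0.1, 0), class = "twosmr_input_error")
  # scale invariance
  for (c_ in c(0.1, 1, 17.3)) {
    expect_equal(f_statistic(c_ * 0.13, c_ * 0.021), f_statistic(0.13, 0.021))
  }
  # a variant exactly at the two-sided p = 5e-8 boundary
  z <- stats::qnorm(1 - 2.5e-8)
  expect_equal(f_statistic(z * 0.02, 0.02), 29.7168, tolerance = 1e-4)
})

test_that("variance explained recovers its algebraic fixed points", {
  n <- 1000
  expect_equal(variance_explained(n - 2, n)$total, 0.5)
  expect_equal(variance_explained(0, n)$total, 0)
  expect_error(variance_explained(10, 2), class = "twosmr_input_error")
  # instrument panel of 77 variants at the reported mean strength
  v <- variance_explained(rep(116.4, 77), 58284)
  expect_gt(v$total, 0.152)
  expect_lt(v$total, 0.154)
})

test_that("greedy clumping keeps the stronger of a correlated pair and spares independent ones", {
  rec <- data.frame(snp_id = c("s1", "s2"), pval = c(1e-10, 1e-9),
                    chrom = "1", pos = c(1e6, 6e6), stringsAsFactors = FALSE)
  ld_hi <- ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2), c("s1", "s2"))
  kept <- suppressMessages(ld_clump(rec, ld_hi))
  expect_equal(kept$snp_id, "s1")
  ld_lo <- ld_matrix(matrix(c(1, 5e-4, 5e-4, 1), 2), c("s1", "s2"))
  expect_equal(suppressMessages(ld_clump(rec, ld_lo))$snp_id, c("s1", "s2"))
})

test_that("clumping with an identity LD matrix is the identity", {
  fix <- make_block_ld_fixture(4, 5, within_r2 = 0, seed = 21)
  rec <- data.frame(snp_id = fix$ld$snp_ids, pval = with_seed_helper(22, runif(20)),
                    chrom = "1", pos = fix$ld$pos, stringsAsFactors = FALSE)
  expect_equal(suppressMessages(ld_clump(rec, fix$ld))$snp_id, rec$snp_id)
})

test_that("clumping a block-diagonal fixture keeps the minimum-p variant per block", {
  fix <- make_block_ld_fixture(4, 5, within_r2 = 0.9, seed = 23)
  rec <- data.frame(snp_id = fix$ld$snp_ids,
                    pval = with_seed_helper(24, 10^-stats::runif(20, 8, 12)),
                    chrom = "1", pos = fix$ld$pos, stringsAsFactors = FALSE)
  kept <- suppressMessages(ld_clump(rec, fix$ld))
  expect_equal(sort(kept$snp_id), oracle_clump_blocks(rec, fix$block))
  expect_equal(nrow(kept), 4)
})

test_that("the clumping window exempts distant same-block pairs", {
  # two variants in perfect LD but 20,000 kb apart: both survive
  rec <- data.frame(snp_id = c("s1", "s2"), pval = c(1e-10, 1e-9),
                    chrom = "1", pos = c(0, 2e7), stringsAsFactors = FALSE)
  ld <- ld_matrix(matrix(c(1, 0.9, 0.9, 1), 2), c("s1", "s2"))
  expect_equal(nrow(suppressMessages(ld_clump(rec, ld))), 2)
  # same pair on different chromosomes: always independent
  rec$pos <- c(1e6, 2e6); rec$chrom <- c("1", "2")
  expect_equal(nrow(suppressMessages(ld_clump(rec, ld))), 2)
})

test_that("clumped output never violates the pairwise r2/window rule", {
  for (seed in 1:20) {
    fix <- make_block_ld_fixture(3, 4, within_r2 = with_seed_helper(seed, runif(1, 0.002, 0.9)),
                                 seed = seed + 100)
    rec <- data.frame(snp_id = fix$ld$snp_ids,
                      pval = with_seed_helper(seed + 200, runif(12)),
                      chrom = "1", pos = fix$ld$pos, stringsAsFactors = FALSE)
    kept <- suppressMessages(ld_clump(rec, fix$ld, r2_threshold = 0.01))
    idx <- match(kept$snp_id, fix$ld$snp_ids)
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-1]) for (b in seq_len(a - 1)) {
        close_enough <- abs(fix$ld$pos[idx[a]] - fix$ld$pos[idx[b]]) <= 1e7
        expect_true(!close_enough || fix$ld$r2[idx[a], idx[b]] < 0.01)
      }
    }
  }
})

test_that("variants absent from the LD matrix are dropped with a warning", {
  rec <- data.frame(snp_id = c("s1", "sX"), pval = c(1e-10, 1e-9),
                    chrom = "1", pos = c(1e6, 2e6), stringsAsFactors = FALSE)
  ld <- ld_matrix(matrix(1), "s1")
  expect_warning(kept <- suppressMessages(ld_clump(rec, ld)), "absent")
  expect_equal(kept$snp_id, "s1")
  expect_error(ld_clump(rec, ld, r2_threshold = 0), class = "twosmr_config_error")
})

test_that("the instrument set applies the F gate and keeps a monotone selection log", {
  h <- sim_harmonized(401, n_snps = 40)
  weak <- h[1, ]
  weak$snp_id <- "rs_weak"
  weak$beta_x <- weak$se_x * 2   # F = 4 < 10
  inst <- suppressMessages(instrument_set(rbind(h, weak)))
  expect_false("rs_weak" %in% inst$pairs$snp_id)
  expect_true(all(inst$f_stats > 10))
  expect_equal(length(inst$f_stats), nrow(inst$pairs))
  # filter counts never increase across the pipeline stages
  pairs <- harmonized_retained(h)
  n0 <- nrow(pairs)
  p1 <- suppressMessages(filter_exposure_significant(pairs))
  p2 <- suppressMessages(exclude_outcome_significant(p1))
  inst2 <- suppressMessages(instrument_set(p2))
  counts <- c(n0, nrow(p1), nrow(p2), nrow(inst2$pairs))
  expect_true(all(diff(counts) <= 0))
})

test_that("LD matrices round trip through square and long text formats", {
  fix <- make_block_ld_fixture(2, 3, within_r2 = 0.4, seed = 31)
  sq <- withr::local_tempfile(fileext = ".tsv")
  m <- fix$ld$r2
  utils::write.table(data.frame(snp = rownames(m), m, check.names = FALSE),
                     sq, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ld_matrix(sq, format = "square")
  expect_equal(back$r2[fix$ld$snp_ids, fix$ld$snp_ids], fix$ld$r2)
  lg <- withr::local_tempfile(fileext = ".tsv")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  utils::write.table(data.frame(snp_a = rownames(m)[idx[, 1]],
                                snp_b = colnames(m)[idx[, 2]],
                                r2 = m[idx]),
                     lg, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_ld_matrix(lg, format = "long")
  expect_equal(back2$r2[fix$ld$snp_ids, fix$ld$snp_ids], fix$ld$r2)
})
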