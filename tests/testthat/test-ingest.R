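make_protein_fixture <- function(path) {
  lines <- c(
    paste("Majority protein IDs", "Gene names", "Reverse",
          "Potential contaminant", "LFQ intensity A", "LFQ intensity B",
          "LFQ intensity C", sep = "\t"),
    paste("P001", "GENE1", "", "", "1000.5", "0", "1200", sep = "\t"),
    paste("P002", "GENE2", "", "+", "500", "600", "700", sep = "\t")
  )
  writeLines(lines, path)
  path
}

test_that("MaxQuant zeros become missing cells and flags parse", {
  path <- make_protein_fixture(withr::local_tempfile(fileext = ".txt"))
  res <- read_maxquant_table(path, "proteinGroups")
  expect_equal(res$table$sample_ids, c("A", "B", "C"))
  expect_equal(sum(res$table$missing_mask), 1)
  expect_true(res$table$missing_mask["B", "P001"])
  expect_equal(res$meta$is_contaminant, c(FALSE, TRUE))
  expect_equal(res$meta$is_reverse, c(FALSE, FALSE))
})

test_that("missing required columns are reported by name", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Gene names\tLFQ intensity A", "x\t1"), path)
  expect_error(read_maxquant_table(path, "proteinGroups"),
               "Majority protein IDs")
  writeLines(c("Majority protein IDs\tGene names", "P1\tG1"), path)
  expect_error(read_maxquant_table(path, "proteinGroups"), "zero samples")
})

test_that("generator output round-trips exactly through the MaxQuant writers", {
  sim <- simulate_abundances(precision_spec(5, n_samples = 8, seed = 2))
  tab <- apply_mnar_censoring(sim$table, 0.2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_maxquant_proteins(tab, path)
  back <- read_maxquant_table(path, "proteinGroups")
  expect_identical(back$table$intensities, tab$intensities)
  expect_identical(back$table$missing_mask, tab$missing_mask)

  prec <- sim$table$intensities[, 1:2]
  colnames(prec) <- c("PA", "PB")
  dig <- simulate_digest(
    digest_spec(c(PA = "AAAAAAAAAAKGGGGGGGGGGG",
                  PB = "CCCCCCCCCCRDDDDDDDDDDD"),
                cleavage_prob = 1, exo_steps = 0, seed = 3), prec)
  ppath <- withr::local_tempfile(fileext = ".txt")
  write_maxquant_peptides(dig$table, ppath, dig$meta)
  pback <- read_maxquant_table(ppath, "peptides")
  expect_identical(pback$table$intensities, dig$table$intensities)
  expect_equal(pback$meta$start, dig$meta$start)
  expect_equal(pback$meta$sequence, dig$meta$sequence)
})

test_that("FASTA round-trips precursor sequences", {
  seqs <- c(PA = "MKTAYIAKQR", PB = "AAAAKRRRRC")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_precursor_fasta(seqs, path)
  expect_identical(read_precursor_fasta(path), seqs)
})

test_that("prevalence filter keeps features present in strictly more than half", {
  # 300 samples: observed in 150 -> dropped, observed in 151 -> kept
  m <- matrix(NA_real_, 300, 3,
              dimnames = list(NULL, c("at150", "at151", "full")))
  m[1:150, 1] <- 2^20
  m[1:151, 2] <- 2^20
  m[, 3] <- 2^20
  out <- filter_features(abundance_table(m))
  expect_setequal(out$feature_ids, c("at151", "full"))
})

test_that("prevalence filter matches a direct count oracle on a toy table", {
  counts <- c(6, 4, 3, 2)
  m <- matrix(NA_real_, 6, 4,
              dimnames = list(NULL, paste0("f", counts)))
  for (j in seq_along(counts)) m[seq_len(counts[j]), j] <- 1
  out <- filter_features(abundance_table(m))
  expect_equal(length(out$feature_ids), sum(counts > 3))
  expect_setequal(out$feature_ids, c("f6", "f4"))
  # with the full-prevalence feature removed, no feature clears 99%
  expect_error(filter_features(abundance_table(m[, c("f4", "f3", "f2")]),
                               min_present_fraction = 0.99),
               "all features removed")
})

test_that("contaminant and reverse features are dropped before prevalence", {
  m <- matrix(2^20, 4, 3, dimnames = list(NULL, c("ok", "con", "rev")))
  meta <- data.frame(feature_id = c("ok", "con", "rev"),
                     is_contaminant = c(FALSE, TRUE, FALSE),
                     is_reverse = c(FALSE, FALSE, TRUE))
  out <- filter_features(abundance_table(m), meta)
  expect_equal(out$feature_ids, "ok")
})

test_that("sample outliers are flagged by log10 margin above the median", {
  m <- matrix(0, 4, 2, dimnames = list(paste0("S", 1:4), NULL))
  totals <- c(1e6, 1.2e6, 0.9e6, 1e9)
  m[, 1] <- totals / 2
  m[, 2] <- totals / 2
  tab <- abundance_table(m)
  expect_equal(flag_outlier_samples(tab), "S4")
  expect_equal(flag_outlier_samples(tab, log10_margin = Inf), character(0))
  same <- abundance_table(matrix(1e6, 4, 2))
  expect_equal(flag_outlier_samples(same), character(0))
})

test_that("imputation is a no-op on complete data and preserves observed cells", {
  sim <- simulate_abundances(precision_spec(6, n_samples = 40, seed = 8))
  expect_identical(impute_mnar(sim$table), sim$table)
  cens <- apply_mnar_censoring(sim$table, 0.25)
  imp <- impute_mnar(cens, seed = 5)
  expect_false(any(imp$missing_mask))
  obs <- !cens$missing_mask
  expect_identical(imp$intensities[obs], cens$intensities[obs])
  # imputed values never exceed the per-feature observed minimum
  for (j in seq_along(cens$feature_ids)) {
    mis <- cens$missing_mask[, j]
    if (!any(mis)) next
    expect_true(all(imp$intensities[mis, j] <=
                      min(cens$intensities[!mis, j])))
  }
  # determinism under a fixed seed
  expect_identical(impute_mnar(cens, seed = 5)$intensities, imp$intensities)
  expect_false(identical(impute_mnar(cens, seed = 6)$intensities,
                         imp$intensities))
})

test_that("imputed values match the truncated-normal mean of the censored tail", {
  # log2 intensities standard normal, censored below the 0.3 quantile;
  # closed-form oracle: E[X | X < q] = -phi(q) / 0.3 for X ~ N(0,1)
  set.seed(77)
  n <- 4000
  z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("A", "B", "C")))
  tab <- apply_mnar_censoring(abundance_table(2^z), 0.3)
  imp <- impute_mnar(tab, seed = 9, n_iterations = 5)
  q <- qnorm(0.3)
  oracle <- -dnorm(q) / 0.3
  for (j in 1:3) {
    mis <- tab$missing_mask[, j]
    expect_lt(abs(mean(log2(imp$intensities[mis, j])) - oracle), 0.15)
  }
})

test_that("imputation requires at least one observed value per feature", {
  m <- matrix(c(NA, NA, 1, 2), 2, 2, dimnames = list(NULL, c("bad", "ok")))
  expect_error(impute_mnar(abundance_table(m)), "bad")
})

test_that("filter -> impute is idempotent on already-complete data", {
  sim <- simulate_abundances(precision_spec(5, n_samples = 30, seed = 12))
  once <- impute_mnar(filter_features(sim$table), seed = 1)
  twice <- impute_mnar(filter_features(once), seed = 1)
  expect_identical(once$intensities, twice$intensities)
})
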