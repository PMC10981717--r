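test_that("independent features give near-zero empirical partial correlations", {
  spec <- precision_spec(n_features = 6, block_sizes = integer(),
                         n_samples = 5000, seed = 11)
  sim <- simulate_abundances(spec)
  res <- partial_correlations(sim$table, lambda = 0)
  off <- res$pcor[upper.tri(res$pcor)]
  expect_true(all(abs(off) < 0.05))
  expect_equal(nrow(sim$truth$true_edges), 0)
})

test_that("planted constant-pcor block reproduces the closed-form rho", {
  # one block of 2 with pcor 0.5 plus an independent feature: the implied
  # partial correlations are rho12 = 0.5, rho13 = rho23 = 0
  spec <- precision_spec(n_features = 3, block_sizes = 2,
                         within_block_pcor = 0.5, n_samples = 5000, seed = 7)
  truth_pcor <- prec_to_pcor(build_precision_oracle(spec))
  expect_equal(truth_pcor[1, 2], 0.5)
  expect_equal(truth_pcor[1, 3], 0)
  sim <- simulate_abundances(spec)
  res <- partial_correlations(sim$table, lambda = 0)
  expect_lt(abs(res$pcor[1, 2] - 0.5), 0.05)
  expect_lt(abs(res$pcor[1, 3]), 0.05)
})

test_that("identical seeds give bit-identical simulations", {
  spec <- precision_spec(10, block_sizes = c(3, 3), within_block_pcor = 0.2,
                         n_samples = 50, seed = 42)
  a <- simulate_abundances(spec)
  b <- simulate_abundances(spec)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$truth$true_edges, b$truth$true_edges)
})

test_that("non-positive-definite block specs are rejected by block index", {
  # a complete block of size 5 with pcor 0.3 violates pcor < 1/(m-1)
  spec <- precision_spec(12, block_sizes = c(3, 5), within_block_pcor = 0.3,
                         n_samples = 50, seed = 1)
  expect_error(simulate_abundances(spec), "block 2")
})

test_that("truth edges are exactly the planted off-diagonal precision entries", {
  spec <- precision_spec(9, block_sizes = c(4, 3), within_block_pcor = 0.2,
                         n_samples = 20, seed = 3)
  sim <- simulate_abundances(spec)
  # block of 4 -> 6 pairs, block of 3 -> 3 pairs
  expect_equal(nrow(sim$truth$true_edges), 9)
  omega <- sim$truth$precision
  expect_equal(sum(omega[upper.tri(omega)] != 0), 9)
  expect_equal(sort(unique(sim$truth$true_clusters)), 1:4)
})

test_that("full-specificity digest emits exactly the inter-K/R fragments", {
  seqs <- c(PR1 = "AAAAAAAKGGGGGGGGRCCCCCCCCC")
  spec <- digest_spec(seqs, cleavage_prob = 1, exo_steps = 0,
                      length_range = c(8, 25), seed = 5)
  prec <- matrix(2^20, 4, 1, dimnames = list(sprintf("S%03d", 1:4), "PR1"))
  dig <- simulate_digest(spec, prec)
  # brute-force oracle: bonds after K (pos 8) and R (pos 17)
  expect_setequal(dig$meta$feature_id, c("PR1_1_8", "PR1_9_17", "PR1_18_26"))
  expect_true(all(vapply(seq_len(nrow(dig$meta)), function(i) {
    substr(seqs[[dig$meta$precursor[i]]], dig$meta$start[i],
           dig$meta$end[i]) == dig$meta$sequence[i]
  }, logical(1))))
  expect_setequal(dig$truth$true_cleavage_sites$bond_position, c(8, 17))
  expect_setequal(dig$truth$true_cleavage_sites$p1_residue, c("K", "R"))
})

test_that("exo trimming adds single-residue ladder variants with lower abundance", {
  seqs <- c(PR1 = "AAAAAAAAAAKGGGGGGGGGGG")  # cut after K at 11
  spec <- digest_spec(seqs, cleavage_prob = 1, exo_steps = 2,
                      length_range = c(8, 25), coupling_sd = 0, seed = 5)
  prec <- matrix(2^20, 3, 1, dimnames = list(sprintf("S%03d", 1:3), "PR1"))
  dig <- simulate_digest(spec, prec)
  # base [1,11] with N-trims [2,11],[3,11] and C-trims [1,10],[1,9];
  # base [12,22] likewise
  expect_true(all(c("PR1_1_11", "PR1_2_11", "PR1_3_11", "PR1_1_10",
                    "PR1_1_9") %in% dig$meta$feature_id))
  base <- dig$table$intensities[1, "PR1_1_11"]
  t1 <- dig$table$intensities[1, "PR1_2_11"]
  t2 <- dig$table$intensities[1, "PR1_3_11"]
  expect_gt(base, t1)
  expect_gt(t1, t2)
  # every peptide is an exact substring at its recorded coordinates
  expect_true(all(vapply(seq_len(nrow(dig$meta)), function(i) {
    substr(seqs[[dig$meta$precursor[i]]], dig$meta$start[i],
           dig$meta$end[i]) == dig$meta$sequence[i]
  }, logical(1))))
  lens <- dig$meta$end - dig$meta$start + 1
  expect_true(all(lens >= 8 & lens <= 25))
})

test_that("zero cleavage probability emits no peptides", {
  spec <- digest_spec(c(PR1 = "AAAAAAAKGGGGGGGG"), cleavage_prob = 0,
                      seed = 2)
  prec <- matrix(2^20, 3, 1, dimnames = list(sprintf("S%03d", 1:3), "PR1"))
  dig <- simulate_digest(spec, prec)
  expect_equal(nrow(dig$meta), 0)
  expect_equal(ncol(dig$table$intensities), 0)
})

test_that("digest rejects invalid residues and empty sequences", {
  expect_error(digest_spec(c(P1 = "AAXK")), "invalid residue")
  expect_error(digest_spec(c(P1 = "")), "empty")
})

test_that("peptide abundance is coupled to precursor abundance", {
  spec <- precision_spec(4, n_samples = 297, seed = 9)
  sim <- simulate_abundances(spec)
  prec_m <- sim$table$intensities[, 1:2]
  colnames(prec_m) <- c("PA", "PB")
  seqs <- c(PA = "AAAAAAAAAAKGGGGGGGGGGGRCCCCCCCCCC",
            PB = "DDDDDDDDDDRHHHHHHHHHHHKEEEEEEEEEE")
  dig <- simulate_digest(digest_spec(seqs, cleavage_prob = 1, exo_steps = 1,
                                     seed = 4), prec_m)
  for (j in seq_len(ncol(dig$table$intensities))) {
    r <- cor(log2(dig$table$intensities[, j]),
             log2(prec_m[, dig$meta$precursor[j]]))
    expect_gte(r, 0.5)
  }
})

test_that("MNAR censoring removes the left tail per feature", {
  set.seed(31)
  m <- matrix(2^rnorm(3000, 20, 2), 1000, 3,
              dimnames = list(sprintf("S%04d", 1:1000), c("A", "B", "C")))
  tab <- abundance_table(m)
  cens <- apply_mnar_censoring(tab, censor_quantile = 0.3)
  for (j in 1:3) {
    miss <- cens$missing_mask[, j]
    expect_equal(sum(miss), 300, tolerance = 0.02)
    thr <- attr(cens, "censor_thresholds")[j]
    expect_true(all(m[miss, j] < thr))
    expect_true(all(m[!miss, j] >= thr))
  }
  # censor_quantile = 0 leaves the table unchanged
  untouched <- apply_mnar_censoring(tab, censor_quantile = 0)
  expect_identical(untouched$intensities, m)
})

test_that("all-constant features are never partially censored", {
  m <- matrix(c(rep(1000, 50), 2^rnorm(50, 20)), 50, 2,
              dimnames = list(NULL, c("const", "var")))
  cens <- apply_mnar_censoring(abundance_table(m), censor_quantile = 0.4)
  n_miss <- sum(cens$missing_mask[, "const"])
  expect_true(n_miss == 0 || n_miss == 50)
})
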