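toy_ladder <- function(cluster = 1) {
  data.frame(cluster = cluster, precursor = "PR1",
             start = c(10, 11, 12, 10, 10),
             end   = c(25, 25, 25, 24, 23))
}

test_that("peptides map to precursor coordinates by exact substring search", {
  prec <- c(PA = "MKTAYIAKQR", PB = "GGGGTAYIGG")
  hit <- map_peptide("TAYI", prec["PA"])
  expect_equal(hit$start, 3)
  expect_equal(hit$end, 6)
  expect_false(hit$ambiguous[1])
  # whole-precursor peptide spans [1, L]
  full <- map_peptide("MKTAYIAKQR", prec["PA"])
  expect_equal(c(full$start, full$end), c(1, 10))
  # multi-hit placements are flagged ambiguous
  multi <- map_peptide("TAYI", prec)
  expect_equal(nrow(multi), 2)
  expect_true(all(multi$ambiguous))
  expect_error(map_peptide("WWWW", prec), "WWWW")
})

test_that("the toy ladder yields one record with the frozen statistics", {
  out <- detect_ladders(toy_ladder())
  expect_equal(nrow(out), 1)
  expect_equal(out$range_start, 10)
  expect_equal(out$range_end, 25)
  expect_equal(out$n_peptides, 5)
  # lengths 16,15,14,15,14 -> mean 74/5 = 14.8
  expect_equal(out$mean_length, 14.8)
})

test_that("components below the threshold or split by gaps are handled", {
  expect_equal(nrow(detect_ladders(toy_ladder()[1:4, ])), 0)
  # two separated ladders on the same precursor within one cluster
  two <- rbind(toy_ladder(),
               data.frame(cluster = 1, precursor = "PR1",
                          start = c(100, 101, 102, 100, 100),
                          end = c(120, 120, 120, 119, 118)))
  out <- detect_ladders(two)
  expect_equal(nrow(out), 2)
  expect_equal(out$range_start, c(10, 100))
  expect_equal(out$range_end, c(25, 120))
  # ladder span is the exact union of member intervals
  expect_true(all(out$range_start == c(min(two$start[1:5]),
                                       min(two$start[6:10]))))
})

test_that("a synthetic BTN1A1-like ladder reproduces Table-2-style statistics", {
  # 19 overlapping peptides spanning 504-526 with total length 283
  # (mean 283/19 = 14.894... -> 14.9)
  lens <- c(23, 22, 20, 18, 16, 15, 15, 15, 14, 14, 14, 13, 13, 12, 12,
            12, 11, 12, 12)
  stopifnot(sum(lens) == 283, length(lens) == 19)
  starts <- pmin(504 + (seq_along(lens) - 1) %% 4, 526 - lens + 1)
  df <- data.frame(cluster = 3, precursor = "BTN1A1_SYN",
                   start = starts, end = starts + lens - 1)
  df$end[1] <- 526  # ensure the union span reaches both bounds
  df$start[1] <- 504
  out <- detect_ladders(df)
  expect_equal(out$range_start, 504)
  expect_equal(out$range_end, 526)
  expect_equal(out$n_peptides, 19)
  expect_equal(out$mean_length, 14.9)
})

test_that("trimming steps find single-residue N- and C-terminal pairs", {
  steps <- trimming_steps(toy_ladder())
  expect_equal(nrow(steps), 4)
  expect_equal(sum(steps$type == "N"), 2)
  expect_equal(sum(steps$type == "C"), 2)
  one <- trimming_steps(data.frame(precursor = "PR1",
                                   start = c(10, 11), end = c(25, 25)))
  expect_equal(one$type, "N")
  # identical coordinates give no pair
  dup <- trimming_steps(data.frame(precursor = "PR1",
                                   start = c(10, 10), end = c(25, 25)))
  expect_equal(nrow(dup), 0)
})

test_that("cleavage specificity matches hand enumeration on AKRLMKGW", {
  prec <- c(PX = "AKRLMKGW")
  peps <- data.frame(precursor = "PX", start = c(4, 4), end = c(6, 7))
  out <- cleavage_specificity(peps, prec)
  # unique bonds after residues 3 (R), 6 (K), 7 (G)
  expect_equal(out$sites$bond_position, c(3, 6, 7))
  expect_equal(out$sites$p1_residue, c("R", "K", "G"))
  expect_equal(unname(out$fractions["plasmin"]), 100 * 2 / 3,
               tolerance = 1e-9)
  # a peptide spanning the whole precursor has no cleavage sites
  whole <- cleavage_specificity(
    data.frame(precursor = "PX", start = 1, end = 8), prec)
  expect_equal(nrow(whole$sites), 0)
  expect_true(is.nan(whole$fractions["plasmin"]))
  expect_error(
    cleavage_specificity(data.frame(precursor = "PX", start = 2, end = 9),
                         prec), "outside")
})

test_that("specificity fractions are invariant to duplicated peptide rows", {
  prec <- c(PX = "AKRLMKGW")
  peps <- data.frame(precursor = "PX", start = c(4, 4, 4), end = c(6, 7, 6))
  out <- cleavage_specificity(peps, prec)
  expect_equal(nrow(out$sites), 3)
  expect_equal(unname(out$fractions["plasmin"]), 100 * 2 / 3,
               tolerance = 1e-9)
})

test_that("pure K/R digests have 100% plasmin specificity and exact site recovery", {
  seqs <- c(PA = "AAAAAAAAAAKGGGGGGGGGGGRCCCCCCCCCC")
  spec <- digest_spec(seqs, cleavage_prob = 1, exo_steps = 0, seed = 6)
  prec <- matrix(2^20, 3, 1, dimnames = list(sprintf("S%03d", 1:3), "PA"))
  dig <- simulate_digest(spec, prec)
  out <- cleavage_specificity(dig$meta, seqs)
  expect_equal(unname(out$fractions["plasmin"]), 100)
  # recovered bond positions equal the generator's planted sites exactly
  expect_setequal(
    paste(out$sites$precursor, out$sites$bond_position),
    paste(dig$truth$true_cleavage_sites$accession,
          dig$truth$true_cleavage_sites$bond_position))
})

test_that("precursor contributions report count and abundance percentages", {
  meta <- data.frame(feature_id = paste0("q", 1:5),
                     precursor = c("A", "A", "A", "B", "C"))
  out <- precursor_contribution(meta)
  expect_equal(out$precursor, c("A", "B", "C"))
  expect_equal(out$count_pct, c(60, 20, 20))
  expect_equal(sum(out$count_pct), 100)
  # single-precursor peptidome
  one <- precursor_contribution(data.frame(precursor = rep("Z", 4)))
  expect_equal(one$count_pct, 100)
  # abundance-based shares from the intensity table
  m <- matrix(rep(c(8, 1, 1, 6, 4), each = 2), 2, 5,
              dimnames = list(NULL, paste0("q", 1:5)))
  tab <- abundance_table(m, kind = "peptide")
  out2 <- precursor_contribution(meta, tab)
  expect_equal(out2$abundance_pct, c(50, 30, 20))
  expect_equal(sum(out2$abundance_pct), 100, tolerance = 0.001)
})

test_that("count-based ranking mirrors a casein-dominated peptidome", {
  # generator proportions shaped like the milk peptidome: one dominant
  # casein-like precursor, then receptor- and membrane-derived peptides
  meta <- data.frame(precursor = rep(c("CSN2", "PIGR", "BTN1A1",
                                       paste0("MINOR", 1:17)),
                                     times = c(77, 21, 17, rep(5, 17))))
  out <- precursor_contribution(meta)
  top3 <- out$precursor[1:3]
  expect_equal(top3[1], "CSN2")
  expect_true(which(out$precursor == "PIGR") <
                which(out$precursor == "BTN1A1"))
})
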