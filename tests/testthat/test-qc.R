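# LD r2, sliding-window pruning, inbreeding F, KING kinship, the
# relatedness filter and its invariants.

test_that("genotype_r2 matches direct Pearson computation and handles edge cases", {
  p <- toy_panel(cbind(c(0L, 1L, 2L, 0L), c(0L, 0L, 2L, 2L),
                       c(0L, 1L, 2L, 0L), c(2L, 1L, 0L, 2L),
                       c(1L, 1L, 1L, 1L)))
  expect_equal(genotype_r2(p, "v1", "v3"), 1)          # identical columns
  expect_equal(genotype_r2(p, "v1", "v4"), 1)          # flipped column, d -> 2-d
  # direct Pearson oracle, written out from the definition
  x <- c(0, 1, 2, 0); y <- c(0, 0, 2, 2)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(genotype_r2(p, "v1", "v2"), r_direct^2)
  expect_true(is.na(genotype_r2(p, "v1", "v5")))       # monomorphic: undefined
})

test_that("genotype_r2 uses pairwise-complete samples", {
  calls <- cbind(c(0L, 1L, 2L, NA, 0L), c(0L, 0L, 2L, 1L, NA))
  p <- toy_panel(calls)
  x <- c(0, 1, 2); y <- c(0, 0, 2)  # rows 1:3 are pairwise complete
  expect_equal(genotype_r2(p, "v1", "v2"), stats::cor(x, y)^2)
})

test_that("LD pruning keeps one of a duplicated pair and respects thresholds", {
  set.seed(21)
  g <- matrix(stats::rbinom(30 * 6, 2, 0.4), nrow = 30)
  g[, 4] <- g[, 3]                                     # duplicated SNP
  p <- toy_panel(g)
  kept <- prune_ld(p)
  expect_true(xor("v3" %in% kept, "v4" %in% kept))
  # independent columns, all pairwise r2 below threshold: all kept
  set.seed(22)
  g2 <- matrix(stats::rbinom(200 * 8, 2, 0.5), nrow = 200)
  p2 <- toy_panel(g2)
  expect_equal(prune_ld(p2), p2$variants$id)
})

test_that("LD pruning matches the exhaustive greedy oracle on 12-SNP panels", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(stats::rbinom(40 * 12, 2, runif(12, 0.2, 0.8)),
                   nrow = 40, byrow = TRUE)
    # induce correlated clumps
    for (j in c(2, 5, 9)) {
      copy_of <- j - 1
      flip <- stats::runif(40) < 0.15
      base[, j] <- ifelse(flip, stats::rbinom(40, 2, 0.5), base[, copy_of])
    }
    p <- toy_panel(base)
    freq <- allele_frequency(p)
    oracle_keep <- oracle_prune(base, pmin(freq, 1 - freq),
                                window_snps = 6, step_snps = 2, r2_max = 0.5)
    kept <- prune_ld(p, window_snps = 6, step_snps = 2, r2_max = 0.5)
    expect_equal(kept, p$variants$id[oracle_keep], info = paste("seed", seed))
  }
})

test_that("LD pruning is invariant to sample order", {
  set.seed(31)
  g <- matrix(stats::rbinom(50 * 20, 2, 0.4), nrow = 50)
  g[, 8] <- g[, 7]; g[, 15] <- pmin(g[, 14] + stats::rbinom(50, 1, 0.1), 2L)
  p <- toy_panel(g)
  perm <- sample(50)
  pp <- genotype_panel(g[perm, ], p$variants,
                       transform(p$samples[perm, ], id = p$samples$id[perm]))
  expect_equal(prune_ld(p), prune_ld(pp))
})

test_that("inbreeding F follows the method-of-moments formula with truncation", {
  set.seed(41)
  p <- balding_nichols_panel(1, 30, 2000, 0, seed = 41)
  res <- inbreeding_F(p)
  # direct recomputation for one sample from the definition
  freq <- allele_frequency(p)
  poly <- freq > 0 & freq < 1
  g <- p$calls[7, poly]
  e_hom <- sum(1 - 2 * freq[poly] * (1 - freq[poly]))
  raw <- (sum(g != 1L) - e_hom) / (sum(!is.na(g)) - e_hom)
  expect_equal(res$raw_F[7], raw)
  expect_equal(res$F, pmax(res$raw_F, 0))              # negative -> 0
  expect_true(any(res$raw_F < 0))                      # truncation exercised
  # fully homozygous sample: raw_F = 1
  p$calls[3, ] <- ifelse(freq > 0.5, 2L, 0L)
  res2 <- inbreeding_F(p)
  expect_equal(res2$raw_F[3], 1, tolerance = 1e-10)
})

test_that("KING kinship: duplicates give 0.5, toy counts match, symmetry holds", {
  # duplicated sample with heterozygous sites
  set.seed(51)
  p <- balding_nichols_panel(1, 10, 500, 0, seed = 51)
  p$calls[2, ] <- p$calls[1, ]
  expect_equal(king_kinship(p, 1, 2)$phi, 0.5)
  # 10-site toy, direct counting oracle
  x <- c(1L, 1L, 1L, 1L, 0L, 2L, 0L, 2L, 1L, 0L)
  y <- c(1L, 0L, 2L, 1L, 2L, 0L, 0L, 2L, 1L, 1L)
  q <- toy_panel(rbind(x, y))
  both_het <- sum(x == 1 & y == 1)
  opp <- sum((x == 0 & y == 2) | (x == 2 & y == 0))
  expect_equal(king_kinship(q, 1, 2)$phi,
               (both_het - 2 * opp) / (sum(x == 1) + sum(y == 1)))
  expect_equal(king_kinship(q, 1, 2)$phi, king_kinship(q, 2, 1)$phi)
  # matrix agrees with the per-pair estimator
  km <- king_kinship_matrix(p)
  expect_equal(km, t(km))
  expect_equal(km[3, 8], king_kinship(p, 3, 8)$phi)
  expect_equal(km[1, 2], 0.5)
})

test_that("independent samples have kinship near zero", {
  p <- balding_nichols_panel(1, 2, 5000, 0, seed = 61)
  expect_lt(abs(king_kinship(p, 1, 2)$phi), 0.05)
})

test_that("kinship handles missing data via pairwise-complete sites", {
  x <- c(1L, NA, 1L, 0L, 2L, NA)
  y <- c(1L, 1L, NA, 2L, 0L, 0L)
  q <- toy_panel(rbind(x, y))
  k <- king_kinship(q, 1, 2)
  expect_equal(k$n_sites, 3L)
  # complete sites: (1,1), (0,2), (2,0): both_het 1, opp 2, het_i 1, het_j 1
  expect_equal(k$phi, (1 - 2 * 2) / (1 + 1))
})

test_that("relatedness filter removes inbred, related and outlier samples", {
  # site count keeps the F estimator's noise well below the 0.0156 threshold
  p <- balding_nichols_panel(1, 40, 20000, 0, seed = 71)
  p <- plant_inbred(p, "POP1_005", 0.02)
  p$calls[12, ] <- p$calls[11, ]                       # duplicate pair
  res <- relatedness_filter(p, pca_outliers = "POP1_030")
  rep <- res$report
  expect_true("POP1_005" %in% rep$sample_id[rep$reason == "inbreeding"])
  expect_gte(rep$value[rep$sample_id == "POP1_005"][1], 0.0156)
  kin_removed <- rep$sample_id[rep$reason == "kinship"]
  expect_length(intersect(kin_removed, c("POP1_011", "POP1_012")), 1)
  expect_true("POP1_030" %in% rep$sample_id[rep$reason == "pca_outlier"])
  expect_false(any(rep$sample_id %in% res$panel$samples$id))
  # post-condition: re-running the estimators finds no violation
  f2 <- inbreeding_F(res$panel)
  expect_true(all(f2$F < 0.0156, na.rm = TRUE))
  km <- king_kinship_matrix(res$panel)
  km[lower.tri(km, diag = TRUE)] <- NA
  expect_true(all(km <= 0.0884, na.rm = TRUE))
})

test_that("kinship threshold zero removes a planted duplicate", {
  p <- balding_nichols_panel(1, 12, 800, 0, seed = 91)
  p$calls[4, ] <- p$calls[3, ]
  res <- relatedness_filter(p, F_max = 1, kin_max = 0)
  kin <- res$report[res$report$reason == "kinship", ]
  expect_true(any(kin$sample_id %in% c("POP1_003", "POP1_004")))
  expect_false(all(c("POP1_003", "POP1_004") %in% res$panel$samples$id))
})

test_that("exempt populations are never removed", {
  p <- balding_nichols_panel(2, 15, 20000, 0.02, seed = 81)
  p$calls[2, ] <- p$calls[1, ]                         # related pair in POP1
  p$calls[17, ] <- p$calls[16, ]                       # related pair in POP2
  res <- relatedness_filter(p, exempt_populations = "POP1")
  expect_false(any(res$report$sample_id %in%
                     p$samples$id[p$samples$population == "POP1"]))
  # the non-exempt pair still loses one member
  expect_length(intersect(res$report$sample_id,
                          c("POP2_001", "POP2_002")), 1)
})
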