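# Recombination-distance bins, LD decay, the Ne formula, trajectories,
# harmonic-mean long-term Ne, and divergence times.

test_that("default bin grid has 246 overlapping bins on the stated grid", {
  b <- make_bins()
  expect_equal(nrow(b), 246L)
  expect_equal(b$start_cM[1], 0.005)
  expect_equal(b$end_cM[1], 0.010)
  expect_equal(b$start_cM[246], 0.250)
  expect_equal(b$c_M, b$mid_cM / 100)
  # width = step gives a disjoint partition
  b2 <- make_bins(step = 0.005, width = 0.005)
  expect_true(all(abs(b2$end_cM[-nrow(b2)] - b2$start_cM[-1]) < 1e-12))
})

test_that("a pair distance falls exactly in the bins that contain it", {
  b <- make_bins()
  d <- 0.0075
  containing <- b$start_cM[d >= b$start_cM - 1e-9 & d < b$end_cM - 1e-9]
  expect_equal(containing, c(0.005, 0.006, 0.007))
})

test_that("perfectly correlated close SNPs give mean r2 = 1 in all containing bins", {
  g <- cbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(0L, 1L, 2L, 0L, 1L, 2L))
  p <- toy_panel(g, pos_cM = c(0.010, 0.018))   # 0.008 cM apart
  ld <- r2_by_distance(p, "P", maf = 0)
  hit <- !is.na(ld$bins$mean_r2)
  d <- 0.018 - 0.010
  expect_equal(ld$bins$start_cM[hit],
               ld$bins$start_cM[d >= ld$bins$start_cM - 1e-9 &
                                  d < ld$bins$end_cM - 1e-9])
  expect_equal(unname(ld$bins$mean_r2[hit]),
               rep(1, sum(hit)), tolerance = 1e-12)
  expect_true(all(ld$bins$n_pairs[hit] == 1))
})

test_that("distant independent SNPs produce no pairs and an empty trajectory", {
  set.seed(201)
  g <- matrix(stats::rbinom(20 * 4, 2, 0.5), nrow = 20)
  p <- toy_panel(g, pos_cM = c(1, 5, 9, 13))    # all gaps > 0.255 cM
  ld <- r2_by_distance(p, "P", maf = 0)
  expect_equal(sum(ld$bins$n_pairs), 0)
  expect_equal(nrow(trajectory(ld)$points), 0L)
})

test_that("binned means match a brute-force pair enumeration oracle", {
  set.seed(202)
  g <- matrix(stats::rbinom(30 * 6, 2, runif(6, 0.2, 0.8)),
              nrow = 30, byrow = TRUE)
  pos <- c(0.0100, 0.0155, 0.0185, 0.0300, 0.1200, 0.2000)
  p <- toy_panel(g, pos_cM = pos)
  bins <- make_bins()
  ld <- r2_by_distance(p, "P", bins, maf = 0)
  # oracle: loop over every pair and every bin directly
  or_sum <- or_cnt <- numeric(nrow(bins))
  for (i in 1:5) for (j in (i + 1):6) {
    d <- pos[j] - pos[i]
    if (stats::sd(g[, i]) == 0 || stats::sd(g[, j]) == 0) next
    r2 <- stats::cor(g[, i], g[, j])^2
    inb <- which(d >= bins$start_cM - 1e-9 & d < bins$end_cM - 1e-9)
    or_sum[inb] <- or_sum[inb] + r2
    or_cnt[inb] <- or_cnt[inb] + 1
  }
  expect_equal(ld$bins$n_pairs, or_cnt)
  expect_equal(ld$bins$mean_r2,
               ifelse(or_cnt > 0, or_sum / or_cnt, NA_real_))
})

test_that("r2 adjustment subtracts 1/n and invalidates empty signal", {
  expect_equal(adjust_r2(0.05, 100), 0.04)
  expect_equal(adjust_r2(0.3, 1e12), 0.3, tolerance = 1e-9)
  expect_true(is.na(adjust_r2(0.005, 100)))     # <= 0: invalid bin
  expect_true(is.na(adjust_r2(0.01, 100)))      # exactly 0 is invalid too
})

test_that("the Ne point formula inverts r2 with flagged negatives", {
  expect_equal(as.numeric(ne_point(0.001, 0.5)), 0)
  expect_equal(as.numeric(ne_point(0.001, 0.05)), (20 - 2) / 0.004)
  expect_equal(as.numeric(ne_point(0.001, 0.05)), 4500)
  r <- seq(0.05, 0.5, by = 0.05)
  ne <- as.numeric(ne_point(0.002, r))
  expect_true(all(diff(ne) < 0))                # decreasing in r2
  expect_true(attr(ne_point(0.001, 0.8), "negative"))
  expect_equal(as.numeric(ne_point(0.001, 0.8)), 0)
})

test_that("trajectory maps distance to time and builds sane intervals", {
  b <- make_bins(start = 0.0475, stop = 0.0476)  # one bin centered at 0.05 cM
  expect_equal(b$t_gen[1], 1000)                 # c = 0.0005 M -> 1/(2c)
  # all pairs identical r2 -> zero-width CI
  g <- cbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(0L, 1L, 2L, 0L, 1L, 2L),
             c(0L, 1L, 2L, 0L, 1L, 2L))
  p <- toy_panel(g, pos_cM = c(0.010, 0.018, 0.026))
  ld <- r2_by_distance(p, "P", maf = 0, n_jk_blocks = 3)
  tr <- trajectory(ld, adjust = FALSE)
  expect_true(all(tr$points$se[!is.na(tr$points$se)] < 1e-10))
  # trajectory times strictly decrease as bin distance grows
  wf <- wf_fixture()
  trw <- trajectory(r2_by_distance(wf$panel, "WF"))
  expect_true(all(diff(trw$points$t_gen) < 0))
  ok <- !is.na(trw$points$se)
  expect_true(all(trw$points$ci_low[ok] <= trw$points$ne[ok] + 1e-9))
  expect_true(all(trw$points$ci_high[ok] >= trw$points$ne[ok] - 1e-9))
})

test_that("long-term Ne is the harmonic mean with AM-HM bounds", {
  # construct an ld_decay whose two bins invert to Ne 4000 and 6000
  b <- make_bins()[c(1, 100), ]
  rownames(b) <- NULL
  c1 <- b$c_M[1]; c2 <- b$c_M[2]
  r1 <- 1 / (4 * c1 * 4000 + 2); r2 <- 1 / (4 * c2 * 6000 + 2)
  ld <- structure(list(
    bins = transform(b, mean_r2 = c(r1, r2), n_pairs = c(10, 10)),
    r2_sum = matrix(c(10 * r1, 10 * r2), 2, 1),
    pair_count = matrix(c(10L, 10L), 2, 1),
    n_samples = 50, population = "T"), class = "ld_decay")
  tr <- trajectory(ld, adjust = FALSE)
  expect_equal(tr$points$ne, c(4000, 6000), tolerance = 1e-9)
  lt <- long_term_ne(tr)
  expect_equal(lt$ne_harmonic, 4800, tolerance = 1e-9)
  expect_equal(lt$ne_harmonic, 2 / (1 / 4000 + 1 / 6000), tolerance = 1e-12)
  expect_lte(lt$ne_harmonic, mean(tr$points$ne))
  # constant trajectory: harmonic mean equals the common value
  wf <- wf_fixture()
  trw <- trajectory(r2_by_distance(wf$panel, "WF"))
  ltw <- long_term_ne(trw)
  expect_lte(ltw$ne_harmonic, mean(trw$points$ne[trw$points$ne > 0]))
})

test_that("divergence time follows the closed form and is invertible", {
  d <- divergence_time(0.1, 5000, 5000)
  expect_equal(d$ne_pair, 5000)
  expect_equal(d$t_generations, log(0.9) / log(1 - 1 / 10000),
               tolerance = 1e-12)
  expect_equal(d$t_generations, 1053.5524754, tolerance = 1e-9)
  expect_equal(d$t_years, d$t_generations * 25)
  expect_equal(divergence_time(0, 5000, 5000)$t_generations, 0)
  # inversion: fst = 1 - (1 - 1/(2Ne))^T recovers the input
  for (fst in c(0.01, 0.1, 0.5, 0.9)) for (ne in c(100, 5000)) {
    t <- divergence_time(fst, ne, ne)$t_generations
    expect_equal(1 - (1 - 1 / (2 * ne))^t, fst, tolerance = 1e-9)
  }
  # monotone in fst and in Ne
  t1 <- divergence_time(0.1, 1000)$t_generations
  expect_gt(divergence_time(0.2, 1000)$t_generations, t1)
  expect_gt(divergence_time(0.1, 2000)$t_generations, t1)
  # harmonic pairing of unequal Ne
  expect_equal(divergence_time(0.1, 4000, 6000)$ne_pair, 4800)
  # negative fst clipped, fst >= 1 rejected
  expect_equal(divergence_time(-0.01, 1000)$t_generations, 0)
  expect_error(divergence_time(1, 1000), "infinite")
})

test_that("divergence matrix is symmetric with near-zero self-divergence", {
  p <- balding_nichols_panel(1, 30, 3000, 0, seed = 203)
  s <- p$samples
  s$population <- rep(c("L1", "L2"), 15)   # same population, two labels
  pp <- genotype_panel(p$calls, p$variants, s)
  dm <- divergence_matrix(pp, c("L1", "L2"), ne = 1000)
  expect_lt(dm$t_generations["L1", "L2"], 30)   # ~0 given clipping/noise
  p3 <- balding_nichols_panel(3, 20, 3000, c(0.02, 0.05, 0.1), seed = 204)
  dm3 <- divergence_matrix(p3, ne = c(POP1 = 1000, POP2 = 1000, POP3 = 1000))
  expect_equal(dm3$t_generations, t(dm3$t_generations))
  expect_equal(unname(diag(dm3$t_generations)), rep(0, 3))
  expect_equal(nrow(dm3$pairs), 3L)
})

test_that("split-pair simulation round-trips through divergence_time", {
  sp <- split_pair_sim(ne = 500, t_gen = 200, n_snps = 8000,
                       n_per_pop = 60, seed = 205)
  fst <- pairwise_fst(sp, "POPA", "POPB", "hudson")$fst_clipped
  t_hat <- divergence_time(fst, 500, 500)$t_generations
  expect_gt(t_hat, 150)
  expect_lt(t_hat, 250)
})
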