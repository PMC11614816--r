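# PLINK and VCF decoding, panel merging, genetic-map annotation.

test_that("PLINK bed decoding matches a hand-decoded fixture and round-trips", {
  dir <- withr::local_tempdir()
  # 3 samples x 2 variants, hand-packed SNP-major bed:
  # variant 1 dosages (2, 1, 0), variant 2 (0, NA, 2).
  # codes (alt dosage 2->00, 1->10, 0->11, NA->01), packed low bits first:
  # v1: s1=00 s2=10 s3=11 pad=00 -> byte 00 11 10 00 = 0x38
  # v2: s1=11 s2=01 s3=00 pad=00 -> byte 00 00 01 11 = 0x07
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x07)),
           file.path(dir, "toy.bed"))
  writeLines(c("1\trs1\t0\t100\tG\tA", "1\trs2\t0\t200\tC\tT"),
             file.path(dir, "toy.bim"))
  writeLines(c("FAM1\tind1\t0\t0\t0\t-9", "FAM1\tind2\t0\t0\t0\t-9",
               "FAM2\tind3\t0\t0\t0\t-9"),
             file.path(dir, "toy.fam"))
  p <- read_plink(file.path(dir, "toy.bed"))
  expect_equal(unname(p$calls),
               matrix(c(2L, 1L, 0L, 0L, NA, 2L), nrow = 3))
  expect_equal(p$samples$id, c("ind1", "ind2", "ind3"))
  expect_equal(p$samples$population, c("FAM1", "FAM1", "FAM2"))
  expect_equal(p$variants$alt, c("G", "C"))
  expect_equal(sum(is.na(p$calls)), 1L)
  expect_true(is.na(p$calls["ind2", "rs2"]))

  write_plink(p, file.path(dir, "rt"))
  expect_identical(readBin(file.path(dir, "rt.bed"), "raw", 100),
                   readBin(file.path(dir, "toy.bed"), "raw", 100))
  p2 <- read_plink(file.path(dir, "rt.bed"))
  expect_identical(p2$calls, p$calls)
  expect_equal(p2$variants[, c("chrom", "pos_bp", "id", "ref", "alt")],
               p$variants[, c("chrom", "pos_bp", "id", "ref", "alt")])
})

test_that("PLINK round-trip preserves larger simulated panels exactly", {
  dir <- withr::local_tempdir()
  p <- balding_nichols_panel(2, 13, 101, 0.1, seed = 5)
  p$calls[cbind(c(1, 5, 13), c(2, 50, 101))] <- NA  # plant missing calls
  write_plink(p, file.path(dir, "sim"))
  q <- read_plink(file.path(dir, "sim.bed"))
  expect_identical(q$calls, p$calls)
  expect_equal(q$variants$pos_bp, p$variants$pos_bp)
  write_plink(q, file.path(dir, "sim2"))
  expect_identical(readBin(file.path(dir, "sim2.bed"), "raw", 1e6),
                   readBin(file.path(dir, "sim.bed"), "raw", 1e6))
})

test_that("bed dimension mismatch is a format error", {
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38)), file.path(dir, "bad.bed"))
  writeLines(c("1\trs1\t0\t100\tG\tA", "1\trs2\t0\t200\tC\tT"),
             file.path(dir, "bad.bim"))
  writeLines(c("F\ti1\t0\t0\t0\t-9", "F\ti2\t0\t0\t0\t-9",
               "F\ti3\t0\t0\t0\t-9"), file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad.bed")), "mismatch")
})

test_that("VCF GT decoding maps dosages, missing and skips multi-allelics", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tr1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tr2\tC\tT\t.\tPASS\t.\tGT\t1|0\t./.\t0/0",
    "1\t300\tr3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"), vcf)
  p <- read_vcf(vcf)
  expect_equal(attr(p, "n_skipped"), 1L)
  expect_equal(n_variants(p), 2L)
  expect_equal(unname(p$calls[, "r1"]), c(0L, 1L, 2L))
  expect_equal(unname(p$calls[, "r2"]), c(1L, NA, 0L))
})

test_that("VCF round-trip through the panel writer preserves calls", {
  dir <- withr::local_tempdir()
  p <- balding_nichols_panel(1, 8, 40, 0.05, seed = 9)
  p$calls[2, 7] <- NA
  write_vcf(p, file.path(dir, "rt.vcf"))
  q <- read_vcf(file.path(dir, "rt.vcf"))
  expect_equal(unname(q$calls), unname(p$calls))
  expect_equal(q$variants$pos_bp, p$variants$pos_bp)
})

make_mergeable <- function(ids, pop, calls, ref = "A", alt = "G",
                           pos = 1000L * seq_len(ncol(calls))) {
  genotype_panel(calls,
                 data.frame(chrom = "1", pos_bp = pos,
                            id = paste0("m", seq_len(ncol(calls))),
                            ref = ref, alt = alt),
                 data.frame(id = ids, population = pop))
}

test_that("merge_panels intersects variants and concatenates samples", {
  a <- make_mergeable(c("a1", "a2"), "A",
                      matrix(c(0L, 1L, 2L, 0L, 1L, 1L, 0L, 2L, 1L, 0L), 2))
  b <- make_mergeable(c("b1", "b2"), "B",
                      matrix(c(2L, 2L, 0L, 1L, 1L, 0L, 2L, 2L, 0L, 1L), 2))
  m <- merge_panels(list(a, b))
  expect_equal(n_variants(m), 5L)
  expect_setequal(m$samples$id, c("a1", "a2", "b1", "b2"))

  # panels sharing 3 of 5 positions
  b3 <- make_mergeable(c("b1", "b2"), "B", b$calls[, 1:3],
                       pos = c(1000L, 3000L, 5000L))
  m3 <- merge_panels(list(a, b3))
  expect_equal(n_variants(m3), 3L)
})

test_that("ref/alt-swapped variants are reconciled by dosage flip", {
  a <- make_mergeable(c("a1", "a2", "a3"), "A",
                      matrix(c(0L, 1L, 2L, 2L, 2L, 0L), 3),
                      ref = "A", alt = "G")
  b <- make_mergeable(c("b1", "b2"), "B",
                      matrix(c(2L, 1L, 0L, 1L), 2),
                      ref = "G", alt = "A")  # swapped orientation
  m <- merge_panels(list(a, b))
  expect_equal(n_variants(m), 2L)
  # after reconciliation both source panels must report the same per-variant
  # frequency they had before the merge (counting the same allele)
  fa_pre <- allele_frequency(a)
  fb_pre <- 1 - allele_frequency(b)  # b counted the other allele
  fa_post <- allele_frequency(m, samples = c("a1", "a2", "a3"))
  fb_post <- allele_frequency(m, samples = c("b1", "b2"))
  canon_flip <- m$variants$alt[1] == "A"
  expect_equal(unname(fa_post), unname(if (canon_flip) 1 - fa_pre else fa_pre))
  expect_equal(unname(fb_post), unname(if (canon_flip) 1 - fb_pre else fb_pre))
})

test_that("merge is symmetric in panel order and rejects duplicates", {
  a <- make_mergeable(c("a1", "a2"), "A", matrix(c(0L, 1L, 2L, 0L), 2))
  b <- make_mergeable(c("b1", "b2"), "B", matrix(c(1L, 1L, 0L, 2L), 2))
  m1 <- merge_panels(list(a, b))
  m2 <- merge_panels(list(b, a))
  expect_equal(m1$calls[sort(rownames(m1$calls)), ],
               m2$calls[sort(rownames(m2$calls)), ])
  expect_equal(m1$variants$pos_bp, m2$variants$pos_bp)
  dup <- make_mergeable(c("a1", "x"), "C", matrix(c(0L, 1L, 2L, 0L), 2))
  expect_error(merge_panels(list(a, dup)), "duplicate sample")
})

test_that("irreconcilable allele pairs are dropped and counted", {
  a <- make_mergeable(c("a1", "a2"), "A", matrix(c(0L, 1L, 2L, 0L), 2),
                      ref = "A", alt = "G")
  b <- make_mergeable(c("b1", "b2"), "B", matrix(c(1L, 1L, 0L, 2L), 2),
                      ref = "A", alt = "C")  # allele mismatch at both sites
  expect_message(m <- merge_panels(list(a, b)), "dropped 2")
  expect_equal(n_variants(m), 0L)
  expect_equal(attr(m, "n_dropped"), 2L)
})

test_that("genetic-map annotation interpolates linearly and clamps", {
  p <- toy_panel(matrix(c(0L, 1L, 2L, 0L), nrow = 1),
                 pos_bp = c(100L, 150L, 200L, 900L))
  map <- genetic_map(data.frame(chrom = "1", pos_bp = c(100L, 200L, 500L),
                                pos_cM = c(1, 3, 3.5)))
  q <- annotate_genetic_positions(p, map)
  expect_equal(q$variants$pos_cM, c(1, 2, 3, 3.5))  # exact, midpoint, clamp
  p2 <- toy_panel(matrix(0:1, 1, 2), chrom = "7")
  expect_error(annotate_genetic_positions(p2, map), "7")
})

test_that("genetic map validates monotonicity", {
  expect_error(genetic_map(data.frame(chrom = "1", pos_bp = c(10L, 10L),
                                      pos_cM = c(0, 1))),
               "strictly increasing")
  expect_error(genetic_map(data.frame(chrom = "1", pos_bp = c(10L, 20L),
                                      pos_cM = c(1, 0))),
               "decreasing")
  dir <- withr::local_tempdir()
  writeLines(c("chrom pos_bp pos_cM", "1 100 0.5", "1 300 1.5"),
             file.path(dir, "map.txt"))
  m <- read_genetic_map(file.path(dir, "map.txt"))
  expect_equal(m$pos_cM, c(0.5, 1.5))
})
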