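#!/usr/bin/env Rscript
# Generate the three synthetic genotype panels every later stage consumes:
#   - a two-population Balding-Nichols panel with known FST = 0.10,
#   - a clean-split drift panel (Ne = 500, T = 200 generations),
#   - a forward Wright-Fisher panel whose LD decay encodes N = 100.
# Panels are written as PLINK filesets plus map and population tables under
# results/sim/.

suppressPackageStartupMessages(library(snpdemog))
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bn <- balding_nichols_panel(n_pops = 2, n_per_pop = 100, n_snps = 20000,
                            fst = 0.10, seed = 1001)
write_plink(bn, file.path(out, "bn_fst10"))
cat("Balding-Nichols panel:", n_samples(bn), "samples x", n_variants(bn),
    "SNPs; monomorphic fraction",
    round(attr(bn, "monomorphic_fraction"), 4), "\n")

sp <- split_pair_sim(ne = 500, t_gen = 200, n_snps = 20000,
                     n_per_pop = 100, seed = 1002)
write_plink(sp, file.path(out, "split_ne500_t200"))
cat("split panel: expected FST", round(1 - (1 - 1 / 1000)^200, 4), "\n")

wf <- wright_fisher_forward(n_diploid = 100, n_generations = 1000,
                            chrom_length_cM = 50, n_sites = 1500,
                            n_chrom = 6, seed = 1003)
write_plink(wf$panel, file.path(out, "wf_n100"))
utils::write.table(wf$map, file.path(out, "wf_n100.map.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wright-Fisher panel:", n_variants(wf$panel),
    "segregating sites on 6 chromosomes\n")

pops <- rbind(bn$samples[, c("id", "population")],
              sp$samples[, c("id", "population")],
              wf$panel$samples[, c("id", "population")])
utils::write.table(pops, file.path(out, "populations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
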