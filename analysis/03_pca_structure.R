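#!/usr/bin/env Rscript
# Patterson-normalized PCA of the two-population panel: the leading
# component should separate the populations completely at FST = 0.10, and
# the explained-variance fractions quantify how much structure the top
# components carry.

suppressPackageStartupMessages(library(snpdemog))
dir.create("results", showWarnings = FALSE)

panel <- read_plink("results/sim/bn_fst10.bed")
pc <- compute_pca(panel, k = 10)
print(pc)

coords <- data.frame(sample = rownames(pc$coordinates),
                     population = panel$samples$population,
                     pc$coordinates)
utils::write.table(coords, "results/pca_coords.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

p1 <- coords$PC1[coords$population == "POP1"]
p2 <- coords$PC1[coords$population == "POP2"]
cat("PC1 separation: POP1 in [", round(min(p1), 2), ",", round(max(p1), 2),
    "], POP2 in [", round(min(p2), 2), ",", round(max(p2), 2), "] -> ",
    ifelse(max(p1) < min(p2) || max(p2) < min(p1),
           "no overlap", "overlap"), "\n")
cat("top-2 explained fraction:",
    round(sum(pc$explained_fraction[1:2]), 4), "\n")

out <- detect_outliers(panel)
cat("PCA outliers flagged:", nrow(out), "\n")
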