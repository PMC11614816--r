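Package: snpdemog
Title: Population Structure and Demographic Inference from SNP Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-structure and demographic analysis of
    diploid biallelic SNP genotype panels: PLINK and VCF input, panel
    merging with allele reconciliation, LD pruning, inbreeding and
    KING-robust kinship quality control, Patterson-normalized principal
    component analysis with iterative outlier removal, pairwise FST
    (Weir-Cockerham and Hudson ratio-of-averages estimators), outgroup
    f3-statistics with weighted block-jackknife errors, LD-decay-based
    effective population size (Ne) trajectories with harmonic-mean
    long-term Ne, FST-based divergence-time estimation, and UPGMA
    population trees. Includes genotype-panel simulators (Balding-Nichols,
    frequency drift after a clean split, and a forward Wright-Fisher model
    with recombination) so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
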