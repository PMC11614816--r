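---
title: "Methods: population structure and demographic inference in snpdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and demographic inference in snpdemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic generators do and do not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The demographic model

The package treats a set of populations as Wright–Fisher demes: discrete
generations, random mating, constant (per-analysis) diploid size Ne, pure
drift. Two consequences of that idealization carry the whole demographic
pipeline:

1. **LD decay encodes Ne.** At drift–recombination equilibrium the
   expected squared correlation of allelic state between loci at
   recombination distance $c$ Morgans falls off as roughly
   $E[r^2] \approx 1/(2 + 4 N_e c)$, inverted as
   $N_e \approx \frac{1}{4c}\left(\frac{1}{r^2} - 2\right)$.
   Because distance $c$ corresponds to a characteristic time depth
   $t = 1/(2c)$ generations, binning pairs by distance yields an Ne
   *trajectory* over past time: short distances probe the deep past, long
   distances the recent past.
2. **FST encodes split time.** After a clean split with no subsequent
   migration, differentiation accumulates as
   $F_{ST} = 1 - (1 - 1/(2N_e))^T$, inverted as
   $T = \ln(1-F_{ST}) / \ln(1 - 1/(2N_e))$ generations, scaled to years
   with 25-year generations.

Both inversions are exact only under the idealization; with migration,
growth, or ascertainment the outputs are index numbers, comparable across
populations analyzed the same way rather than literal census history.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| LD-pruning window / step / threshold | 50 / 5 / 0.5 | SNPs, r² | the classic pairwise-independence pruning configuration |
| inbreeding removal | F ≥ 0.0156 | — | second-cousin-offspring expectation |
| kinship removal | φ > 0.0884 | — | second-degree boundary of the KING scale |
| PCA outliers | 6 SD, 10 PCs, 5 rounds | — | the EIGENSOFT-style default |
| distance bins | 0.005–0.25 cM, step 0.001, width 0.005 | cM | overlapping categories spanning t ≈ 200–6,700 generations |
| r² sample adjustment | subtract 1/n | — | first-order sampling inflation of squared correlation |
| Ne-stage MAF filter | 0.10 | — | see below |
| jackknife blocks | 20 contiguous genomic blocks (Ne); 5 cM or 50 equal-count (f3) | — | robust to local LD |
| generation length | 25 | years | standard human value |

Two defaults deserve their own paragraphs.

**The bin grid.** Starts run from 0.005 to 0.25 cM in 0.001 cM steps with
width 0.005 cM, giving 246 overlapping bins; each bin's representative
distance is its midpoint. The grid is often described as "250
categories", but 0.005..0.250 by 0.001 yields 246 starts; the package
implements the stated grid and reports the count it actually has. The
width (five times the step) is configurable; overlap smooths the
trajectory at the cost of correlated neighboring bins, which is why
confidence intervals come from genomic blocks of *pairs* rather than from
bin-to-bin scatter.

**The MAF filter for the Ne stage.** The equilibrium inversion assumes
loci whose alleles are old enough to have accumulated drift-generated
association. Rare alleles are young: their $r^2$ with neighbors is close
to zero regardless of Ne, so including them dilutes the bin means and
biases Ne upward. `r2_by_distance()` therefore excludes variants with
minor allele frequency below 0.10 by default — the conventional cutoff for
LD-based Ne estimation at modest sample sizes — and exposes `maf` for
users whose panels are already ascertained to common variants (set
`maf = 0` to keep everything polymorphic).

## Estimator choices

* **FST** is always ratio-of-averages (sum of per-variant numerators over
  sum of denominators), never an average of per-variant ratios, for both
  Weir–Cockerham (1984, the default) and Hudson. The two differ by well
  under their own standard errors on the simulated panels; the estimates
  are reported unclipped (small negatives are estimator noise), with a
  zero-clipped companion value that feeds the divergence formula. A
  caveat discovered while testing: for two "populations" that are
  literally the same individuals duplicated, neither estimator returns
  exactly zero — the unbiased within-population variance corrections make
  the numerator slightly negative. Near-zero, not zero, is the correct
  expectation there.
* **f3** is the plain shared-drift form without the finite-sample
  heterozygosity correction, because the package uses it for *ranking*
  shared drift; variants monomorphic across the three populations are
  excluded, which is what makes the statistic invariant to padding a
  panel with monomorphic sites.
* **Kinship** is the KING-robust within-pair estimator
  $(N_{het,het} - 2N_{opp.hom}) / (N^i_{het} + N^j_{het})$, chosen
  because it needs no population allele frequencies and is therefore
  robust to structure.
* **Inbreeding F** is the method-of-moments excess-homozygosity estimator.
  The filter evaluates it *within each sample's population* by default:
  against pooled frequencies of a structured panel every sample shows
  excess homozygosity of about the between-population FST (the Wahlund
  effect) and the 0.0156 threshold would flag everyone. Pooled behavior
  is available (`within_populations = FALSE`) for homogeneous panels.
* **The pair Ne** entering the divergence formula is the harmonic mean of
  the two populations' long-term Ne — the formula has a single Ne and some
  pairing rule is required; the harmonic mean is the natural choice for a
  rate-like quantity and reduces to either value when they are equal.
* **Confidence intervals** use the weighted delete-one-block jackknife
  (Busing et al. 1999): blocks are contiguous stretches of genome, so the
  resampling respects local LD; the weighted form handles unequal block
  sizes. For Ne the deletion propagates through the bin means, the 1/n
  adjustment, the Ne formula, and (for long-term Ne) the harmonic mean.

## Numerical and degenerate-input rules

* Bin membership uses a $10^{-9}$ cM tolerance at the interval edges so
  that distances which are exact bin boundaries in real arithmetic land in
  the bins a textbook reading of $[s, s+w)$ assigns, despite floating
  point.
* Undefined quantities are `NA` and excluded, never coerced to zero:
  monomorphic variants in r² and PCA normalization, bins with no pairs,
  adjusted r² ≤ 0, kinship pairs with no heterozygous sites.
* r² > 0.5 inverts to a negative Ne; such bins report Ne = 0, are
  flagged, and are excluded from the harmonic mean.
* Negative FST is clipped to zero before the divergence logarithm; FST ≥ 1
  is an error (infinite divergence).
* UPGMA resolves distance ties by the lexicographic order of the
  competing pairs' smallest member labels, and the Newick writer orders
  children by subtree label, so the output is byte-deterministic and
  invariant to input permutation.
* Panel merging keys variants on (chromosome, position), reconciles
  ref/alt swaps by flipping dosage ($d \to 2-d$), stores a canonical
  allele orientation so the merge is symmetric in panel order, and drops
  (with a count) allele pairs that neither match nor swap — including
  strand-ambiguous A/T and C/G conflicts, whose orientation cannot be
  established without strand information.
* Genetic positions are interpolated linearly in bp between map points
  and clamped at map boundaries; extrapolation could produce negative or
  runaway genetic positions.

## What the generators emulate — and what they do not

`balding_nichols_panel()` draws per-population allele frequencies from a
Beta distribution around a Uniform(0.05, 0.95) ancestral frequency with
variance parameter equal to the target FST, then samples
Hardy–Weinberg genotypes. It emulates *differentiation* exactly but
carries no linkage at all, so it tests FST, f3, PCA, and kinship — not
the Ne machinery.

`split_pair_sim()` drifts frequencies for T binomial rounds in two
daughters of size Ne. Drift acts on frequencies, not individuals —
exact for the FST/T relation and orders of magnitude faster — so it tests
divergence-time recovery, again without LD.

`wright_fisher_forward()` is the individual-based simulator for the LD
machinery: diploid Wright–Fisher with Poisson crossovers on a uniform
map (1 cM per Mb), burn-in of at least 10N generations, and recurrent
mutation that re-seeds any fixed or lost site from a single copy, keeping
the number of segregating sites constant. Two deliberate simplifications:
the site-frequency spectrum is the mutation–drift equilibrium one (young,
rare alleles are common — the reason the Ne stage filters on MAF), and
when several chromosomes are requested they are simulated as independent
replicates rather than co-segregating through one pedigree. The
independence matters: along a single chromosome all pairs share one
realized genealogy, so per-bin means fluctuate together between
replicates and precision grows with the number of independent
chromosomes, not with site density — which is also why real LD-based Ne
estimation is a genome-wide affair.

Passing parameter-recovery tests on these generators shows the estimators
are correct *under the model*; it does not certify behavior under
ascertainment bias, genotyping error, migration, or non-equilibrium
demography, all of which real panels have.

## Problem sizes used in the tests and acceptance runs

Simulated panels are sized so each quantity's sampling noise is small
against the property being asserted: 20,000 unlinked SNPs with 100
samples per population for FST and split-time recovery (FST standard
error ≈ 0.002 at truth 0.10), 1,500 segregating sites per chromosome on
six 50-cM chromosomes of a size-100 Wright–Fisher population for Ne
recovery, and 20,000 sites wherever the inbreeding threshold 0.0156 must
sit several standard errors above estimator noise (the F estimator's
standard error is ≈ 0.008 at that size; the study-scale panels this
mirrors carry hundreds of thousands of sites, where the threshold is
sharp).

## Known limitations

* Ne trajectories inherit every assumption of the equilibrium inversion;
  recent admixture or strong growth distorts them in known directions
  (admixture-LD inflates r², biasing Ne down at the corresponding
  depths).
* Divergence times assume no post-split gene flow; with migration they
  are lower bounds in expectation.
* The merge has no liftover, no multi-allelic support, and no strand
  flipping by allele-frequency matching.
* PCA offers no projection of one panel onto another's axes (no
  lsqproject analogue) and no shrinkage correction.
* The pipeline's f3 scan requires an explicit outgroup population; it is
  skipped when none is configured.
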