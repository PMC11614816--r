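# Per-variant allele counts for one population subset: alt count, observed
# allele count (2 x non-missing), het proportion among observed genotypes.
pop_counts <- function(panel, pop) {
  si <- population_samples(panel, pop)
  g <- panel$calls[si, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  list(n_ind = n_obs,
       p = colSums(g, na.rm = TRUE) / (2 * n_obs),
       het = colSums(g == 1L, na.rm = TRUE) / n_obs)
}

#' Pairwise FST between two populations
#'
#' Ratio-of-averages estimators (sum of per-variant numerators over sum of
#' denominators -- never an average of per-variant ratios):
#' \itemize{
#'   \item \code{"wc"}: Weir & Cockerham's (1984) theta, from the a, b, c
#'     variance components with observed heterozygosity.
#'   \item \code{"hudson"}: \eqn{N = (p_1 - p_2)^2 - p_1(1-p_1)/(n_1-1)
#'     - p_2(1-p_2)/(n_2-1)}, \eqn{D = p_1(1-p_2) + p_2(1-p_1)}, with
#'     \eqn{n} the observed allele counts.
#' }
#' Variants monomorphic across the union, or with fewer than two genotyped
#' samples in either population, are excluded. Small negative estimates are
#' estimator noise and are reported unclipped, with \code{fst_clipped}
#' (truncated at 0) for downstream divergence-time use.
#'
#' @param panel a \code{genotype_panel}.
#' @param popA,popB population labels.
#' @param estimator \code{"wc"} (default) or \code{"hudson"}.
#' @return list of class \code{fst_result}: \code{popA}, \code{popB},
#'   \code{fst}, \code{fst_clipped}, \code{n_sites}, \code{estimator}.
#' @export
pairwise_fst <- function(panel, popA, popB, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ca <- pop_counts(panel, popA)
  cb <- pop_counts(panel, popB)
  use <- ca$n_ind >= 2 & cb$n_ind >= 2
  p_all <- (ca$p * ca$n_ind + cb$p * cb$n_ind) / (ca$n_ind + cb$n_ind)
  use <- use & !is.na(p_all) & p_all > 0 & p_all < 1
  if (!any(use)) stop("no usable variants for ", popA, " vs ", popB)
  n1 <- ca$n_ind[use]; n2 <- cb$n_ind[use]
  p1 <- ca$p[use]; p2 <- cb$p[use]
  if (estimator == "hudson") {
    a1 <- 2 * n1; a2 <- 2 * n2   # allele counts
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (a1 - 1) - p2 * (1 - p2) / (a2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- sum(num) / sum(den)
  } else {
    h1 <- ca$het[use]; h2 <- cb$het[use]
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    fst <- sum(a) / sum(a + b + cc)
  }
  structure(list(popA = popA, popB = popB, fst = fst,
                 fst_clipped = max(fst, 0), n_sites = sum(use),
                 estimator = estimator),
            class = "fst_result")
}

#' FST matrix over populations
#'
#' @param panel a \code{genotype_panel}.
#' @param populations labels; default all populations in the panel.
#' @param estimator passed to \code{\link{pairwise_fst}}.
#' @param clipped return the zero-truncated values (default TRUE, the form
#'   consumed by divergence-time estimation).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
fst_matrix <- function(panel, populations = NULL,
                       estimator = c("wc", "hudson"), clipped = TRUE) {
  estimator <- match.arg(estimator)
  if (is.null(populations)) populations <- unique(panel$samples$population)
  k <- length(populations)
  out <- matrix(0, k, k, dimnames = list(populations, populations))
  if (k < 2) return(out)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- pairwise_fst(panel, populations[i], populations[j], estimator)
    out[i, j] <- out[j, i] <- if (clipped) f$fst_clipped else f$fst
  }
  out
}

#' Per-variant outgroup f3 values
#'
#' \eqn{(o - a)(o - b)} per variant: the shared drift of A and B relative to
#' the outgroup. Symmetric in A and B.
#'
#' @param freq_o,freq_a,freq_b allele-frequency vectors at shared variants.
#' @return numeric vector of per-variant values.
#' @export
outgroup_f3 <- function(freq_o, freq_a, freq_b) {
  stopifnot(length(freq_o) == length(freq_a),
            length(freq_o) == length(freq_b))
  (freq_o - freq_a) * (freq_o - freq_b)
}

#' Weighted delete-one-block jackknife
#'
#' Point estimate (the overall mean of the per-variant values) and standard
#' error from leaving out one block at a time, with unequal block sizes
#' handled by the weighted jackknife of Busing et al. (1999), the convention
#' of the standard f-statistics tools. With equal weights and constant
#' values the estimate is the plain mean and the SE is 0.
#'
#' @param values per-variant values.
#' @param blocks block assignment (factor-like), same length as
#'   \code{values}.
#' @param weights per-block weights in block-level order
#'   (\code{sort(unique(blocks))}); default the block variant counts.
#' @return list \code{estimate}, \code{se}, \code{n_blocks}; \code{se} is
#'   \code{NA} (flagged) with fewer than 2 blocks.
#' @export
block_jackknife <- function(values, blocks, weights = NULL) {
  stopifnot(length(values) == length(blocks))
  blocks <- as.factor(blocks)
  bl <- levels(droplevels(blocks))
  g <- length(bl)
  sums <- tapply(values, blocks, sum)[bl]
  cnts <- tapply(values, blocks, length)[bl]
  if (is.null(weights)) weights <- as.numeric(cnts)
  stopifnot(length(weights) == g)
  n <- sum(weights)
  tot <- sum(sums)
  theta <- tot / sum(cnts)
  if (g < 2)
    return(list(estimate = theta, se = NA_real_, n_blocks = g))
  theta_minus <- (tot - sums) / (sum(cnts) - cnts)
  h <- n / weights
  theta_J <- g * theta - sum((1 - weights / n) * theta_minus)
  pseudo <- h * theta - (h - 1) * theta_minus
  var_J <- sum((pseudo - theta_J)^2 / (h - 1)) / g
  list(estimate = theta, se = sqrt(var_J), n_blocks = g)
}

# Assign variants to jackknife blocks: contiguous ~size_cM blocks per
# chromosome when genetic positions are available, else n_blocks equal-count
# blocks over the variant order.
jackknife_blocks <- function(panel, size_cM = 5, n_blocks = 50) {
  v <- panel$variants
  if (!anyNA(v$pos_cM)) {
    blk <- paste(v$chrom, floor(v$pos_cM / size_cM), sep = "_")
  } else {
    nb <- min(n_blocks, nrow(v))
    blk <- as.character(ceiling(seq_len(nrow(v)) / (nrow(v) / nb)))
  }
  blk
}

#' Outgroup f3 statistic with block-jackknife error
#'
#' Computes f3(outgroup; A, B) as the mean per-variant shared drift
#' \eqn{(o-a)(o-b)}, with a weighted block jackknife over genomic blocks
#' (5 cM by genetic position when the panel is map-annotated, otherwise 50
#' equal-count blocks). Variants monomorphic across the union of the three
#' populations, or unobserved in any of them, are excluded -- adding globally
#' monomorphic variants therefore cannot move the statistic. No
#' finite-sample heterozygosity correction is applied: the statistic is used
#' for relative ranking of shared drift, for which the uncorrected form
#' suffices.
#'
#' @param panel a \code{genotype_panel}.
#' @param outgroup,popA,popB population labels.
#' @param block_cM jackknife block size in cM.
#' @param n_blocks fallback equal-count block number without a map.
#' @return list of class \code{f3_result}: \code{outgroup}, \code{popA},
#'   \code{popB}, \code{f3}, \code{se}, \code{z}, \code{n_sites},
#'   \code{n_blocks}.
#' @export
f3_stat <- function(panel, outgroup, popA, popB, block_cM = 5,
                    n_blocks = 50) {
  fo <- allele_frequency(panel, samples = population_samples(panel, outgroup))
  fa <- allele_frequency(panel, samples = population_samples(panel, popA))
  fb <- allele_frequency(panel, samples = population_samples(panel, popB))
  ok <- !is.na(fo) & !is.na(fa) & !is.na(fb) & !is.nan(fo) & !is.nan(fa) &
    !is.nan(fb)
  mono <- ok & ((fo == 0 & fa == 0 & fb == 0) | (fo == 1 & fa == 1 & fb == 1))
  use <- ok & !mono
  if (!any(use)) stop("no shared polymorphic variants for f3(",
                      outgroup, "; ", popA, ", ", popB, ")")
  vals <- outgroup_f3(fo[use], fa[use], fb[use])
  blk <- jackknife_blocks(panel, size_cM = block_cM, n_blocks = n_blocks)[use]
  jk <- block_jackknife(vals, blk)
  structure(list(outgroup = outgroup, popA = popA, popB = popB,
                 f3 = jk$estimate, se = jk$se,
                 z = if (!is.na(jk$se) && jk$se > 0) jk$estimate / jk$se
                 else NA_real_,
                 n_sites = sum(use), n_blocks = jk$n_blocks),
            class = "f3_result")
}

#' Outgroup-f3 scan over source/target population pairs
#'
#' One \code{\link{f3_stat}} row per (source, target) combination, in the
#' form (outgroup; source, target).
#'
#' @param panel a \code{genotype_panel}.
#' @param outgroup outgroup population label.
#' @param source_pops,target_pops population label vectors.
#' @param ... passed to \code{\link{f3_stat}}.
#' @return data.frame with columns \code{source}, \code{target}, \code{f3},
#'   \code{se}, \code{z}, \code{n_sites}, \code{n_blocks}, sortable by
#'   \code{f3}.
#' @export
f3_scan <- function(panel, outgroup, source_pops, target_pops, ...) {
  grid <- expand.grid(source = source_pops, target = target_pops,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    f <- f3_stat(panel, outgroup, grid$source[r], grid$target[r], ...)
    data.frame(source = grid$source[r], target = grid$target[r],
               f3 = f$f3, se = f$se, z = f$z, n_sites = f$n_sites,
               n_blocks = f$n_blocks)
  })
  do.call(rbind, rows)
}
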