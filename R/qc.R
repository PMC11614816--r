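#' Genotype LD r-squared between two variants
#'
#' Squared Pearson correlation of alt-allele dosage vectors over
#' pairwise-complete samples. This is the phase-free (composite) LD measure;
#' no haplotype phasing or EM frequency estimation is involved.
#'
#' @param panel a \code{genotype_panel}.
#' @param a,b variant ids or indices.
#' @param samples sample subset (ids, mask or indices); default all.
#' @return r-squared in [0, 1], or \code{NA} if either variant is monomorphic
#'   in the subset or fewer than 2 pairwise-complete samples remain
#'   (undefined, to be excluded -- never coerced to zero).
#' @export
genotype_r2 <- function(panel, a, b, samples = NULL) {
  si <- resolve_index(samples, panel$samples$id, "sample")
  ai <- resolve_index(a, panel$variants$id, "variant")
  bi <- resolve_index(b, panel$variants$id, "variant")
  x <- panel$calls[si, ai]
  y <- panel$calls[si, bi]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# All pairwise dosage r^2 within a window of variant indices, over a fixed
# sample subset. Pairwise-complete; NA where undefined.
r2_matrix <- function(calls) {
  m <- ncol(calls)
  if (anyNA(calls)) {
    out <- matrix(NA_real_, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      ok <- !is.na(calls[, i]) & !is.na(calls[, j])
      if (sum(ok) < 2) next
      x <- calls[ok, i]; y <- calls[ok, j]
      if (stats::var(x) == 0 || stats::var(y) == 0) next
      out[i, j] <- out[j, i] <- stats::cor(x, y)^2
    }
    diag(out) <- 1
    return(out)
  }
  sds <- apply(calls, 2, stats::sd)
  r <- suppressWarnings(stats::cor(calls))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  r^2
}

#' Sliding-window LD pruning
#'
#' Greedy window pruning with the classic 50-SNP window / 5-SNP step / r2 0.5
#' defaults. Windows slide over the variant index within each chromosome;
#' within a window, while any pair of still-kept variants has r2 above the
#' threshold, the pair with the highest r2 is resolved by removing its
#' lower-MAF member (tie: the variant at the later position). Deterministic
#' and invariant to sample order.
#'
#' @param panel a \code{genotype_panel} (variants sorted by chrom, pos).
#' @param window_snps window size in SNPs.
#' @param step_snps step size in SNPs.
#' @param r2_max r-squared threshold above which a pair is violating.
#' @param samples sample subset used to estimate r2 and MAF; default all.
#' @return character vector of kept variant ids, in panel order.
#' @export
prune_ld <- function(panel, window_snps = 50, step_snps = 5, r2_max = 0.5,
                     samples = NULL) {
  si <- resolve_index(samples, panel$samples$id, "sample")
  p <- allele_frequency(panel, samples = si)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, n_variants(panel))
  for (ch in unique(panel$variants$chrom)) {
    vidx <- which(panel$variants$chrom == ch)
    nv <- length(vidx)
    starts <- if (nv <= window_snps) 0L else
      seq(0L, nv - 1L, by = step_snps)
    for (s in starts) {
      win <- vidx[(s + 1):min(s + window_snps, nv)]
      win <- win[keep[win]]
      if (length(win) < 2) next
      r2 <- r2_matrix(panel$calls[si, win, drop = FALSE])
      diag(r2) <- NA
      repeat {
        viol <- which(!is.na(r2) & r2 > r2_max, arr.ind = TRUE)
        if (!nrow(viol)) break
        viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
        best <- order(-r2[viol], viol[, 1], viol[, 2])[1]
        i <- viol[best, 1]; j <- viol[best, 2]
        drop_local <- if (maf[win[i]] < maf[win[j]]) i
        else if (maf[win[j]] < maf[win[i]]) j
        else j  # equal MAF: drop the later position
        keep[win[drop_local]] <- FALSE
        r2[drop_local, ] <- NA
        r2[, drop_local] <- NA
      }
    }
  }
  panel$variants$id[keep]
}

#' Method-of-moments inbreeding coefficients
#'
#' Per sample, over its non-missing sites:
#' \deqn{\hat F_{raw} = (O_{hom} - E_{hom}) / (L - E_{hom})}
#' where \eqn{E_{hom} = \sum_k (1 - 2 p_k (1 - p_k))} uses the whole-panel
#' allele frequencies. Negative values are truncated to zero in \code{F}
#' (they reflect sampling error); the untruncated value is kept in
#' \code{raw_F}. Samples with \eqn{L - E_{hom}} numerically zero are flagged
#' undefined.
#'
#' @param panel a \code{genotype_panel}.
#' @return data.frame with columns \code{sample_id}, \code{F}, \code{raw_F},
#'   \code{n_sites}, \code{defined}.
#' @export
inbreeding_F <- function(panel) {
  p <- allele_frequency(panel)
  poly <- !is.na(p) & p > 0 & p < 1
  g <- panel$calls[, poly, drop = FALSE]
  e_site <- 1 - 2 * p[poly] * (1 - p[poly])
  obs <- !is.na(g)
  L <- rowSums(obs)
  O_hom <- rowSums(g == 0L | g == 2L, na.rm = TRUE)
  E_hom <- as.vector(obs %*% e_site)
  denom <- L - E_hom
  defined <- abs(denom) > 1e-8
  raw <- ifelse(defined, (O_hom - E_hom) / denom, NA_real_)
  data.frame(sample_id = panel$samples$id,
             F = pmax(raw, 0),
             raw_F = raw,
             n_sites = L,
             defined = defined)
}

#' KING-robust kinship for one sample pair
#'
#' Within-pair estimator from heterozygote and opposite-homozygote counts
#' over pairwise-complete sites:
#' \deqn{\phi = (N_{het,het} - 2 N_{opp.hom}) / (N_{het}^i + N_{het}^j)}
#' A duplicated sample gives 0.5; unrelated samples scatter around 0;
#' second-degree relatives exceed 0.0884.
#'
#' @param panel a \code{genotype_panel}.
#' @param i,j sample ids or indices.
#' @return list with \code{phi}, \code{n_sites} (pairwise-complete count) and
#'   \code{defined} (FALSE when neither sample has a heterozygous site, in
#'   which case the pair is treated as unrelated).
#' @export
king_kinship <- function(panel, i, j) {
  ii <- resolve_index(i, panel$samples$id, "sample")
  jj <- resolve_index(j, panel$samples$id, "sample")
  x <- panel$calls[ii, ]
  y <- panel$calls[jj, ]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  both_het <- sum(x == 1L & y == 1L)
  opp_hom <- sum((x == 0L & y == 2L) | (x == 2L & y == 0L))
  het_i <- sum(x == 1L)
  het_j <- sum(y == 1L)
  denom <- het_i + het_j
  list(phi = if (denom > 0) (both_het - 2 * opp_hom) / denom else NA_real_,
       n_sites = sum(ok),
       defined = denom > 0)
}

#' KING-robust kinship matrix for all sample pairs
#'
#' Vectorized computation of the same estimator as \code{\link{king_kinship}}
#' for every pair; exactly symmetric.
#'
#' @param panel a \code{genotype_panel}.
#' @return symmetric numeric matrix of phi values (NA where undefined),
#'   with sample ids as dimnames.
#' @export
king_kinship_matrix <- function(panel) {
  g <- panel$calls
  obs <- !is.na(g)
  H <- (g == 1L) & obs; storage.mode(H) <- "double"; H[is.na(H)] <- 0
  A0 <- (g == 0L) & obs; storage.mode(A0) <- "double"; A0[is.na(A0)] <- 0
  A2 <- (g == 2L) & obs; storage.mode(A2) <- "double"; A2[is.na(A2)] <- 0
  Ob <- obs; storage.mode(Ob) <- "double"
  both_het <- tcrossprod(H)
  opp <- tcrossprod(A0, A2)
  opp <- opp + t(opp)
  het_i <- tcrossprod(H, Ob)    # sites het in row sample & observed in col
  denom <- het_i + t(het_i)
  phi <- (both_het - 2 * opp) / denom
  phi[denom == 0] <- NA
  dimnames(phi) <- list(panel$samples$id, panel$samples$id)
  phi
}

#' Remove inbred, related and outlying samples
#'
#' Applies, in order: (1) the inbreeding filter, removing samples with
#' \eqn{F \ge} \code{F_max}; (2) the kinship filter, removing from each
#' remaining pair with \eqn{\phi >} \code{kin_max} the member with more
#' missing calls (tie: the later sample in panel order); (3) removal of the
#' listed PCA outliers. Samples from \code{exempt_populations} are never
#' removed. Inbreeding uses the original panel's allele frequencies; no
#' iterative re-estimation. By default F is evaluated within each sample's
#' own population: against pooled frequencies of a structured panel, every
#' sample shows excess homozygosity of roughly the between-population FST
#' (the Wahlund effect) and would be flagged spuriously.
#'
#' @param panel a \code{genotype_panel}.
#' @param F_max inbreeding threshold (removal at F >= F_max).
#' @param kin_max kinship threshold (removal at phi > kin_max).
#' @param pca_outliers sample ids to remove as PCA outliers.
#' @param exempt_populations population labels never filtered.
#' @param within_populations compute inbreeding per population (default)
#'   rather than against pooled panel frequencies.
#' @return list with \code{panel} (filtered) and \code{report} (data.frame
#'   \code{sample_id}, \code{reason}, \code{value}).
#' @export
relatedness_filter <- function(panel, F_max = 0.0156, kin_max = 0.0884,
                               pca_outliers = character(),
                               exempt_populations = character(),
                               within_populations = TRUE) {
  exempt <- panel$samples$population %in% exempt_populations
  names(exempt) <- panel$samples$id
  report <- data.frame(sample_id = character(), reason = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  fres <- if (within_populations) {
    do.call(rbind, lapply(unique(panel$samples$population), function(pp)
      inbreeding_F(subset_panel(panel, samples =
                                  population_samples(panel, pp)))))
  } else inbreeding_F(panel)
  drop_f <- fres$sample_id[!is.na(fres$F) & fres$F >= F_max &
                             !exempt[fres$sample_id]]
  if (length(drop_f))
    report <- rbind(report, data.frame(
      sample_id = drop_f, reason = "inbreeding",
      value = fres$F[match(drop_f, fres$sample_id)]))
  kept <- setdiff(panel$samples$id, drop_f)
  sub <- subset_panel(panel, samples = kept)
  phi <- king_kinship_matrix(sub)
  miss <- sample_missingness(sub)
  ord <- stats::setNames(seq_len(n_samples(sub)), sub$samples$id)
  repeat {
    phi_v <- phi
    phi_v[lower.tri(phi_v, diag = TRUE)] <- NA
    viol <- which(!is.na(phi_v) & phi_v > kin_max, arr.ind = TRUE)
    if (nrow(viol)) {
      ex_i <- exempt[rownames(phi)[viol[, 1]]]
      ex_j <- exempt[colnames(phi)[viol[, 2]]]
      viol <- viol[!(ex_i & ex_j), , drop = FALSE]
    }
    if (!nrow(viol)) break
    i <- rownames(phi)[viol[1, 1]]
    j <- colnames(phi)[viol[1, 2]]
    cand <- c(i, j)[!exempt[c(i, j)]]
    drop <- if (length(cand) == 1) cand
    else if (miss[i] != miss[j]) c(i, j)[which.max(c(miss[i], miss[j]))]
    else c(i, j)[which.max(c(ord[i], ord[j]))]
    report <- rbind(report, data.frame(
      sample_id = drop, reason = "kinship", value = phi[i, j]))
    ki <- match(drop, rownames(phi))
    phi <- phi[-ki, -ki, drop = FALSE]
  }
  kept <- intersect(kept, rownames(phi))
  drop_pca <- intersect(pca_outliers, kept)
  drop_pca <- drop_pca[!exempt[drop_pca]]
  if (length(drop_pca))
    report <- rbind(report, data.frame(
      sample_id = drop_pca, reason = "pca_outlier", value = NA_real_))
  kept <- setdiff(kept, drop_pca)
  list(panel = subset_panel(panel, samples = kept), report = report)
}
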