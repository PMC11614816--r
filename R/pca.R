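#' Patterson-normalize a genotype panel
#'
#' Each dosage is centered and scaled by its variant's binomial standard
#' deviation: \eqn{(d - 2p) / \sqrt{2 p (1 - p)}}, with p the alt-allele
#' frequency over the used samples. Monomorphic (and all-missing) variants
#' are dropped; missing entries become 0 after centering (mean imputation,
#' the standard choice for this normalization).
#'
#' @param panel a \code{genotype_panel}.
#' @param samples sample subset; default all.
#' @return numeric matrix (samples x kept variants) with attribute
#'   \code{n_dropped} (monomorphic variants removed).
#' @export
normalize_panel <- function(panel, samples = NULL) {
  si <- resolve_index(samples, panel$samples$id, "sample")
  p <- allele_frequency(panel, samples = si)
  keep <- !is.na(p) & p > 0 & p < 1
  g <- panel$calls[si, keep, drop = FALSE]
  pk <- p[keep]
  x <- sweep(g, 2, 2 * pk, "-")
  x <- sweep(x, 2, sqrt(2 * pk * (1 - pk)), "/")
  x[is.na(x)] <- 0
  rownames(x) <- panel$samples$id[si]
  attr(x, "n_dropped") <- sum(!keep)
  x
}

#' Principal component analysis of a genotype panel
#'
#' Eigendecomposition of the sample x sample covariance of the
#' Patterson-normalized matrix. Explained fractions are eigenvalues divided
#' by the trace (the full spectrum sums to 1). Eigenvector signs are
#' arbitrary, as always.
#'
#' @param panel a \code{genotype_panel}.
#' @param k number of components to return (truncated to the rank, with a
#'   warning, when larger).
#' @param samples sample subset; default all.
#' @return list of class \code{panel_pca} with \code{coordinates}
#'   (samples x k, columns \code{PC1..PCk}), \code{explained_fraction},
#'   \code{eigenvalues} (full spectrum) and \code{samples}.
#' @export
compute_pca <- function(panel, k = 10, samples = NULL) {
  x <- normalize_panel(panel, samples = samples)
  n <- nrow(x)
  if (n < 2 || ncol(x) < 2)
    stop("need >= 2 samples and >= 2 polymorphic variants")
  cov <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 explained_fraction = ev[seq_len(k)] / sum(ev),
                 eigenvalues = ev,
                 samples = rownames(x)),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("panel_pca:", length(x$samples), "samples,",
      ncol(x$coordinates), "components\n")
  cat("explained fraction:",
      paste(sprintf("%.3f", x$explained_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Iterative PCA outlier detection
#'
#' Flags samples whose coordinate on any of the top \code{n_pcs} components
#' exceeds \code{n_sd} standard deviations of that component, then recomputes
#' the PCA without them and repeats, up to \code{max_iter} rounds (the
#' EIGENSOFT-style default of 6 SD over 10 PCs for 5 iterations).
#'
#' @param panel a \code{genotype_panel}.
#' @param n_sd standard-deviation threshold.
#' @param n_pcs number of leading components examined.
#' @param max_iter maximum removal rounds.
#' @param samples sample subset; default all.
#' @return data.frame \code{sample_id}, \code{iteration}; zero rows when no
#'   outliers.
#' @export
detect_outliers <- function(panel, n_sd = 6, n_pcs = 10, max_iter = 5,
                            samples = NULL) {
  si <- resolve_index(samples, panel$samples$id, "sample")
  current <- panel$samples$id[si]
  out <- data.frame(sample_id = character(), iteration = integer())
  for (it in seq_len(max_iter)) {
    if (length(current) < 3) break
    pc <- tryCatch(
      suppressWarnings(compute_pca(panel, k = n_pcs, samples = current)),
      error = function(e) NULL)
    if (is.null(pc)) break
    co <- pc$coordinates
    sds <- apply(co, 2, stats::sd)
    usable <- sds > 0
    if (!any(usable)) break
    z <- sweep(sweep(co[, usable, drop = FALSE], 2,
                     colMeans(co[, usable, drop = FALSE]), "-"),
               2, sds[usable], "/")
    flagged <- rownames(co)[apply(abs(z) > n_sd, 1, any)]
    if (!length(flagged)) break
    out <- rbind(out, data.frame(sample_id = flagged, iteration = it))
    current <- setdiff(current, flagged)
  }
  out
}
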