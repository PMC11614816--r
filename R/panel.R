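#' Construct a genotype panel
#'
#' A genotype panel holds diploid biallelic SNP calls as an integer matrix of
#' alt-allele dosages (samples in rows, variants in columns) together with
#' variant and sample metadata. Missing calls are stored as \code{NA}.
#'
#' @param calls integer matrix, samples x variants, values in \{0, 1, 2, NA\}.
#' @param variants data.frame with columns \code{chrom}, \code{pos_bp},
#'   \code{id}, \code{ref}, \code{alt} and optionally \code{pos_cM}
#'   (genetic position in centimorgans, \code{NA} until map-annotated).
#' @param samples data.frame with columns \code{id}, \code{population} and
#'   optionally \code{tags} (free-form grouping labels).
#' @return An object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(variants$pos_cM)) variants$pos_cM <- NA_real_
  if (is.null(samples$tags)) samples$tags <- ""
  req_v <- c("chrom", "pos_bp", "id", "ref", "alt")
  if (!all(req_v %in% names(variants)))
    stop("variants must have columns: ", paste(req_v, collapse = ", "))
  if (!all(c("id", "population") %in% names(samples)))
    stop("samples must have columns: id, population")
  if (nrow(samples) != nrow(calls) || nrow(variants) != ncol(calls))
    stop("calls matrix is ", nrow(calls), "x", ncol(calls),
         " but there are ", nrow(samples), " samples and ",
         nrow(variants), " variants")
  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("calls must be in {0, 1, 2, NA}")
  if (any(variants$pos_bp < 1L))
    stop("pos_bp must be >= 1")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ (variant ",
         variants$id[which(variants$ref == variants$alt)[1]], ")")
  o <- order(variants$chrom, variants$pos_bp)
  if (is.unsorted(o)) {
    variants <- variants[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  rownames(calls) <- samples$id
  colnames(calls) <- variants$id
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  pops <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat("missing calls:", sum(is.na(x$calls)), "\n")
  has_cm <- sum(!is.na(x$variants$pos_cM))
  cat("variants with genetic position:", has_cm, "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$samples), nrow(x$variants))

#' Number of samples / variants in a panel
#' @param panel a \code{genotype_panel}.
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Subset a panel by samples and/or variants
#'
#' @param panel a \code{genotype_panel}.
#' @param samples sample ids, logical mask, or integer indices; \code{NULL}
#'   keeps all.
#' @param variants variant ids, logical mask, or integer indices; \code{NULL}
#'   keeps all.
#' @return a \code{genotype_panel}.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- resolve_index(samples, panel$samples$id, "sample")
  vi <- resolve_index(variants, panel$variants$id, "variant")
  genotype_panel(panel$calls[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.logical(idx)) {
    stopifnot(length(idx) == length(ids))
    return(which(idx))
  }
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(m)) stop("unknown ", what, " id(s): ",
                       paste(idx[is.na(m)], collapse = ", "))
    return(m)
  }
  as.integer(idx)
}

#' Sample indices belonging to a population
#' @param panel a \code{genotype_panel}.
#' @param population population label(s).
#' @return integer vector of row indices into the calls matrix.
#' @export
population_samples <- function(panel, population) {
  idx <- which(panel$samples$population %in% population)
  if (!length(idx)) stop("no samples in population(s): ",
                         paste(population, collapse = ", "))
  idx
}

#' Alt-allele frequencies
#'
#' Per-variant alternate-allele frequency: alt-allele count divided by twice
#' the number of non-missing calls. Variants with no non-missing call in the
#' subset get \code{NaN} (undefined; excluded downstream).
#'
#' @param panel a \code{genotype_panel}.
#' @param variants variants to use (ids, mask or indices); default all.
#' @param samples samples to use (ids, mask or indices); default all.
#' @return named numeric vector of frequencies in [0, 1].
#' @export
allele_frequency <- function(panel, variants = NULL, samples = NULL) {
  si <- resolve_index(samples, panel$samples$id, "sample")
  vi <- resolve_index(variants, panel$variants$id, "variant")
  g <- panel$calls[si, vi, drop = FALSE]
  n_obs <- colSums(!is.na(g))
  colSums(g, na.rm = TRUE) / (2 * n_obs)
}

#' Per-sample missing-call counts
#' @param panel a \code{genotype_panel}.
#' @return named integer vector, one entry per sample.
#' @export
sample_missingness <- function(panel) {
  out <- rowSums(is.na(panel$calls))
  names(out) <- panel$samples$id
  out
}
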