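# Fixture builders and independent oracles shared across test files.

# Small panel from an explicit dosage matrix (samples x variants).
toy_panel <- function(calls, pos_bp = 1000L * seq_len(ncol(calls)),
                      chrom = "1", pos_cM = NA_real_,
                      populations = "P") {
  n <- nrow(calls)
  m <- ncol(calls)
  genotype_panel(
    calls,
    data.frame(chrom = chrom, pos_bp = pos_bp,
               id = paste0("v", seq_len(m)), ref = "A", alt = "G",
               pos_cM = pos_cM),
    data.frame(id = paste0("s", seq_len(n)),
               population = rep_len(populations, n)))
}

# The Wright-Fisher fixture is expensive; compute once per session.
wf_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- wright_fisher_forward(n_diploid = 100, n_generations = 1000,
                                      chrom_length_cM = 50, n_sites = 1500,
                                      n_chrom = 6, seed = 42)
    cache
  }
})

# --- independent oracles (deliberately naive re-implementations) ------------

# Exhaustive greedy LD pruning with the documented removal rule, coded
# directly from the rule description (no shared code with prune_ld).
oracle_prune <- function(calls, maf, window_snps, step_snps, r2_max) {
  m <- ncol(calls)
  keep <- rep(TRUE, m)
  starts <- if (m <= window_snps) 0L else seq(0L, m - 1L, by = step_snps)
  pair_r2 <- function(i, j) {
    x <- calls[, i]; y <- calls[, j]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }
  for (s in starts) {
    repeat {
      win <- intersect((s + 1):min(s + window_snps, m), which(keep))
      if (length(win) < 2) break
      worst <- NULL
      for (a in seq_along(win)[-length(win)]) for (b in (a + 1):length(win)) {
        r2 <- pair_r2(win[a], win[b])
        if (!is.na(r2) && r2 > r2_max &&
            (is.null(worst) || r2 > worst$r2 + 1e-15))
          worst <- list(r2 = r2, i = win[a], j = win[b])
      }
      if (is.null(worst)) break
      drop <- if (maf[worst$i] < maf[worst$j]) worst$i
      else if (maf[worst$j] < maf[worst$i]) worst$j
      else worst$j
      keep[drop] <- FALSE
    }
  }
  keep
}

# Naive O(n^3) UPGMA with the same merge/tie rules, tracked as flat merge
# records; returns the cophenetic distance matrix it implies.
oracle_upgma_cophenetic <- function(d, labels) {
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  minlab <- labels
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  dd <- d
  for (step in seq_len(n - 1)) {
    best <- NULL
    idx <- which(alive)
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      key <- paste(sort(c(minlab[i], minlab[j])), collapse = "\r")
      if (is.null(best) || dd[i, j] < best$d - 1e-15 ||
          (abs(dd[i, j] - best$d) <= 1e-15 && key < best$key))
        best <- list(d = dd[i, j], i = i, j = j, key = key)
    }
    i <- best$i; j <- best$j
    for (a in members[[i]]) for (b in members[[j]])
      coph[a, b] <- coph[b, a] <- best$d
    for (m in idx) {
      if (m == i || m == j) next
      dd[i, m] <- dd[m, i] <-
        (sizes[i] * dd[i, m] + sizes[j] * dd[j, m]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    minlab[i] <- min(minlab[i], minlab[j])
    sizes[i] <- sizes[i] + sizes[j]
    alive[j] <- FALSE
  }
  coph
}

# Cophenetic matrix of an upgma_tree: distance between two leaves is twice
# the height of their most recent common ancestor.
tree_cophenetic <- function(tree) {
  leaves <- sort(tree_leaves(tree))
  coph <- matrix(0, length(leaves), length(leaves),
                 dimnames = list(leaves, leaves))
  rec <- function(node) {
    if (is.null(node$children)) return(node$label)
    kids <- lapply(node$children, rec)
    for (a in seq_along(kids)[-length(kids)])
      for (b in (a + 1):length(kids))
        for (x in kids[[a]]) for (y in kids[[b]])
          coph[x, y] <<- coph[y, x] <<- 2 * node$height
    unlist(kids)
  }
  rec(tree)
  coph
}

# Random ultrametric-consistent distance matrix: random binary tree with
# increasing merge heights, returned as its distance matrix.
random_ultrametric <- function(n_taxa, labels = LETTERS[seq_len(n_taxa)]) {
  groups <- as.list(labels)
  h <- 0
  d <- matrix(0, n_taxa, n_taxa, dimnames = list(labels, labels))
  while (length(groups) > 1) {
    h <- h + stats::runif(1, 0.5, 2)
    pick <- sample(length(groups), 2)
    for (x in groups[[pick[1]]]) for (y in groups[[pick[2]]])
      d[x, y] <- d[y, x] <- 2 * h
    groups <- c(groups[-pick], list(c(groups[[pick[1]]], groups[[pick[2]]])))
  }
  d
}

# Plant an inbred copy of a sample: flip heterozygous sites to homozygous
# until the target method-of-moments F is reached (deterministic). F is
# targeted on the sample's own population frequencies, matching how the
# relatedness filter evaluates it.
plant_inbred <- function(panel, sample_id, target_F) {
  si <- match(sample_id, panel$samples$id)
  pop <- panel$samples$population[si]
  p <- allele_frequency(panel, samples = which(panel$samples$population == pop))
  poly <- !is.na(p) & p > 0 & p < 1
  e_hom <- sum(1 - 2 * p[poly] * (1 - p[poly]))
  g <- panel$calls[si, poly]
  L <- sum(!is.na(g))
  o_hom <- sum(g == 0L | g == 2L, na.rm = TRUE)
  need <- ceiling(target_F * (L - e_hom) + e_hom - o_hom)
  het <- which(panel$calls[si, ] == 1L)[seq_len(max(need, 0))]
  panel$calls[si, het] <- ifelse(p[het] > 0.5, 2L, 0L)
  panel
}
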