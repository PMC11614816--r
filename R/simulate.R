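#' Simulate a structured panel under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each
#' population's frequency is drawn Beta(p(1-F)/F, (1-p)(1-F)/F), so that the
#' between-population variance at a site equals F p(1-p) -- F is the target
#' FST. Genotypes are Binomial(2, p_pop). With F = 0 the population frequency
#' equals the ancestral frequency exactly.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid samples per population (recycled over pops).
#' @param n_snps number of unlinked variants.
#' @param fst target FST per population (scalar or per-pop vector).
#' @param seed integer seed; the draw is deterministic given it.
#' @param pop_names population labels; default \code{POP1..POPk}.
#' @return a \code{genotype_panel}; variants are placed on one chromosome at
#'   1 kb spacing with no genetic map.
#' @export
balding_nichols_panel <- function(n_pops = 2, n_per_pop = 100, n_snps = 5000,
                                  fst = 0.1, seed,
                                  pop_names = paste0("POP", seq_len(n_pops))) {
  stopifnot(n_pops >= 1, all(n_per_pop >= 1), n_snps >= 1,
            all(fst >= 0), all(fst < 1))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst <- rep_len(fst, n_pops)
  p_anc <- stats::runif(n_snps, 0.05, 0.95)
  calls <- matrix(NA_integer_, nrow = sum(n_per_pop), ncol = n_snps)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    f <- fst[k]
    p_pop <- if (f == 0) p_anc else
      stats::rbeta(n_snps, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    g <- matrix(stats::rbinom(n_per_pop[k] * n_snps, 2L,
                              rep(p_pop, each = n_per_pop[k])),
                nrow = n_per_pop[k])
    calls[row0 + seq_len(n_per_pop[k]), ] <- g
    row0 <- row0 + n_per_pop[k]
  }
  samples <- data.frame(
    id = sprintf("%s_%03d", rep(pop_names, n_per_pop),
                 unlist(lapply(n_per_pop, seq_len))),
    population = rep(pop_names, n_per_pop))
  variants <- data.frame(chrom = "1", pos_bp = 1000L * seq_len(n_snps),
                         id = sprintf("snp%06d", seq_len(n_snps)),
                         ref = "A", alt = "G")
  panel <- genotype_panel(calls, variants, samples)
  attr(panel, "monomorphic_fraction") <- monomorphic_fraction(panel)
  panel
}

# fraction of sites with no variation in the emitted panel (reported so
# downstream invariance to monomorphic sites can be checked)
monomorphic_fraction <- function(panel) {
  f <- allele_frequency(panel)
  mean(f == 0 | f == 1, na.rm = TRUE)
}

#' Simulate a clean two-population split by frequency drift
#'
#' The model under which the divergence-time relation
#' \eqn{F_{ST} = 1 - (1 - 1/(2N_e))^T} is exact: an ancestral frequency
#' (Uniform(0.05, 0.95)) evolves independently in two daughter populations of
#' constant diploid size \code{ne} for \code{t_gen} rounds of binomial drift
#' (\eqn{p' = \mathrm{Bin}(2N_e, p)/(2N_e)}); genotypes are then sampled from
#' the final frequencies. Drift acts on frequencies, not individuals, so the
#' panel carries no LD -- use \code{\link{wright_fisher_forward}} when linkage
#' matters.
#'
#' @param ne diploid effective size of each daughter population.
#' @param t_gen generations since the split.
#' @param n_snps number of unlinked variants.
#' @param n_per_pop diploid samples drawn per population.
#' @param seed integer seed.
#' @param pop_names two population labels.
#' @return a \code{genotype_panel} with two populations. The expected FST is
#'   \code{1 - (1 - 1/(2*ne))^t_gen}.
#' @export
split_pair_sim <- function(ne = 500, t_gen = 200, n_snps = 20000,
                           n_per_pop = 100, seed,
                           pop_names = c("POPA", "POPB")) {
  stopifnot(ne >= 50, t_gen >= 0)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  p_anc <- stats::runif(n_snps, 0.05, 0.95)
  drift <- function(p) {
    for (g in seq_len(t_gen)) p <- stats::rbinom(n_snps, 2L * ne, p) / (2 * ne)
    p
  }
  p1 <- drift(p_anc)
  p2 <- drift(p_anc)
  calls <- rbind(
    matrix(stats::rbinom(n_per_pop * n_snps, 2L, rep(p1, each = n_per_pop)),
           nrow = n_per_pop),
    matrix(stats::rbinom(n_per_pop * n_snps, 2L, rep(p2, each = n_per_pop)),
           nrow = n_per_pop))
  samples <- data.frame(
    id = sprintf("%s_%03d", rep(pop_names, each = n_per_pop),
                 rep(seq_len(n_per_pop), 2)),
    population = rep(pop_names, each = n_per_pop))
  variants <- data.frame(chrom = "1", pos_bp = 1000L * seq_len(n_snps),
                         id = sprintf("snp%06d", seq_len(n_snps)),
                         ref = "A", alt = "G")
  panel <- genotype_panel(calls, variants, samples)
  attr(panel, "monomorphic_fraction") <- monomorphic_fraction(panel)
  panel
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete-generation diploid Wright-Fisher population of constant size
#' \code{n_diploid}. Each offspring draws two parents at random; each gamete
#' recombines the parent's two haplotypes with a Poisson number of crossovers
#' (mean = map length in Morgans, crossover positions uniform on the map).
#' Sites are kept segregating by recurrent mutation: after each generation,
#' any site fixed or lost is re-seeded by flipping one randomly chosen
#' haplotype, so the panel always carries \code{n_sites} segregating sites
#' (young re-seeded alleles are rare and fall below the usual MAF filters).
#' After burn-in the LD decay with recombination distance encodes the true
#' \code{n_diploid}, which the trajectory estimator should recover.
#'
#' @param n_diploid diploid population size N (>= 20); all N individuals are
#'   emitted as the sample.
#' @param n_generations generations to evolve; at least 10N is required so LD
#'   reaches drift-recombination equilibrium.
#' @param chrom_length_cM genetic length of each simulated chromosome.
#' @param n_sites number of segregating sites maintained per chromosome.
#' @param seed integer seed.
#' @param n_chrom number of independently simulated chromosomes. LD
#'   fluctuations are strongly correlated along one chromosome (all site
#'   pairs share the population's realized genealogy), so per-bin precision
#'   grows with independent chromosomes, not with site density; genome-wide
#'   LD-based Ne estimation relies on exactly this averaging.
#' @param population label for the emitted samples.
#' @return list with \code{panel} (a \code{genotype_panel}, cM-annotated) and
#'   \code{map} (the uniform \code{genetic_map} used: 1 cM per Mb).
#' @export
wright_fisher_forward <- function(n_diploid = 100,
                                  n_generations = 10 * n_diploid,
                                  chrom_length_cM = 50, n_sites = 1500,
                                  seed, n_chrom = 1, population = "WF") {
  stopifnot(n_diploid >= 20, chrom_length_cM > 0, n_sites >= 2,
            n_chrom >= 1)
  if (n_generations < 10 * n_diploid)
    stop("n_generations must be >= 10 * n_diploid (burn-in to LD equilibrium)")
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  chroms <- lapply(seq_len(n_chrom), function(ch)
    wf_sim_chrom(n_diploid, n_generations, chrom_length_cM, n_sites))
  calls <- do.call(cbind, lapply(chroms, `[[`, "calls"))
  variants <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    v <- chroms[[ch]]$variants
    v$chrom <- as.character(ch)
    v$id <- sprintf("wf%d_%06d", ch, seq_len(nrow(v)))
    v
  }))
  samples <- data.frame(id = sprintf("%s_%03d", population,
                                     seq_len(n_diploid)),
                        population = population)
  panel <- genotype_panel(calls, variants, samples)
  attr(panel, "monomorphic_fraction") <- monomorphic_fraction(panel)
  map <- genetic_map(do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    bp <- c(1L, max(chroms[[ch]]$variants$pos_bp) + 1L)
    data.frame(chrom = as.character(ch), pos_bp = bp,
               pos_cM = (bp - 1L) / 1e6)
  })))
  list(panel = panel, map = map)
}

# One chromosome of the forward simulation, drawn from the current RNG
# stream.
wf_sim_chrom <- function(n_diploid, n_generations, chrom_length_cM,
                         n_sites) {
  n_hap <- 2L * n_diploid
  pos_cM <- sort(stats::runif(n_sites, 0, chrom_length_cM))
  len_M <- chrom_length_cM / 100
  # initial standing variation: independent sites at uniform frequencies
  p0 <- stats::runif(n_sites, 0.05, 0.95)
  H <- matrix(stats::rbinom(n_hap * n_sites, 1L, rep(p0, each = n_hap)),
              nrow = n_hap)
  for (gen in seq_len(n_generations)) {
    parent <- sample.int(n_diploid, n_hap, replace = TRUE)
    start <- sample.int(2L, n_hap, replace = TRUE) - 1L   # 0/1 starting hap
    k <- stats::rpois(n_hap, len_M)
    src <- 2L * parent - 1L + start
    Hn <- H[src, , drop = FALSE]                           # no-crossover copy
    for (g in which(k > 0L)) {
      bp <- sort(stats::runif(k[g], 0, chrom_length_cM))
      use2 <- (start[g] + findInterval(pos_cM, bp)) %% 2L == 1L
      if (any(use2)) Hn[g, use2] <- H[2L * parent[g] - 1L + 1L, use2]
      if (!all(use2)) Hn[g, !use2] <- H[2L * parent[g] - 1L, !use2]
    }
    H <- Hn
    cs <- colSums(H)
    mono <- which(cs == 0L | cs == n_hap)
    if (length(mono)) {
      flip_row <- sample.int(n_hap, length(mono), replace = TRUE)
      H[cbind(flip_row, mono)] <- 1L - H[cbind(flip_row, mono)]
    }
  }
  calls <- H[seq(1, n_hap, by = 2), , drop = FALSE] +
    H[seq(2, n_hap, by = 2), , drop = FALSE]
  pos_bp <- as.integer(round(pos_cM * 1e6)) + 1L          # 1 cM per Mb
  # enforce strictly increasing bp for map validity
  pos_bp <- pos_bp + seq_len(n_sites) - 1L
  list(calls = calls,
       variants = data.frame(chrom = "1", pos_bp = pos_bp, id = "",
                             ref = "A", alt = "G", pos_cM = pos_cM))
}
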