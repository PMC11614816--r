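#' Overlapping recombination-distance bins
#'
#' The grid of recombination-distance categories over which LD decay is
#' summarized: bins \code{[s, s + width)} for starts \code{s = start,
#' start + step, ..., stop}. With the defaults (start 0.005, stop 0.25, step
#' 0.001, width 0.005 cM) consecutive bins overlap five-fold and there are
#' 246 bins. Each bin's representative distance is its midpoint, in Morgans
#' (\code{c_M = mid_cM / 100}), and maps to time \code{t = 1/(2 c)}
#' generations in the past.
#'
#' @param start,stop first and last bin start, in cM.
#' @param step start-to-start increment, in cM.
#' @param width bin width, in cM.
#' @return data.frame with columns \code{start_cM}, \code{end_cM},
#'   \code{mid_cM}, \code{c_M}, \code{t_gen}.
#' @export
make_bins <- function(start = 0.005, stop = 0.25, step = 0.001,
                      width = 0.005) {
  stopifnot(start > 0, start < stop, step > 0, width > 0)
  s <- seq(start, stop, by = step)
  mid <- s + width / 2
  data.frame(start_cM = s, end_cM = s + width, mid_cM = mid,
             c_M = mid / 100, t_gen = 100 / (2 * mid))
}

#' Mean LD r-squared per recombination-distance bin
#'
#' For every intra-chromosomal variant pair whose cM distance falls inside a
#' bin, the pair's genotype r-squared (over the population subset)
#' contributes to that bin's mean; because bins overlap, a pair contributes
#' to every bin containing its distance. Variants must be map-annotated.
#' Variants below the MAF threshold are excluded: the equilibrium inversion
#' behind the Ne formula assumes alleles old enough to carry drift-generated
#' LD, and rare alleles are young, so they dilute mean r-squared and bias Ne
#' upward; 0.10 is the conventional cutoff for LD-based Ne estimation with
#' modest sample sizes.
#' Pairs are also assigned to contiguous genomic jackknife blocks (by the
#' left variant) so downstream Ne confidence intervals can delete one block
#' at a time.
#'
#' @param panel a cM-annotated \code{genotype_panel}.
#' @param population population label; its samples define the r2 subset.
#' @param bins bin grid from \code{\link{make_bins}}.
#' @param maf minor-allele-frequency threshold (set 0 to keep all
#'   polymorphic variants).
#' @param n_jk_blocks number of contiguous genomic jackknife blocks.
#' @return list of class \code{ld_decay}: \code{bins} (the grid plus
#'   \code{mean_r2}, \code{n_pairs}; bins with no pairs have \code{NA}),
#'   \code{r2_sum}, \code{pair_count} (bin x block matrices),
#'   \code{n_samples}, \code{population}.
#' @export
r2_by_distance <- function(panel, population, bins = make_bins(),
                           maf = 0.1, n_jk_blocks = 20) {
  si <- population_samples(panel, population)
  if (anyNA(panel$variants$pos_cM))
    stop("panel is not fully map-annotated (pos_cM has NA); ",
         "run annotate_genetic_positions() first")
  p <- allele_frequency(panel, samples = si)
  keep <- !is.na(p) & pmin(p, 1 - p) >= max(maf, .Machine$double.eps)
  vidx <- which(keep)
  n <- length(si)
  step <- bins$start_cM[2] - bins$start_cM[1]
  width <- bins$end_cM[1] - bins$start_cM[1]
  k_over <- round(width / step)
  lo <- bins$start_cM[1]
  hi <- bins$end_cM[nrow(bins)]
  nb <- nrow(bins)
  # contiguous equal-count genomic blocks over the kept variant order
  blk_of <- ceiling(seq_along(vidx) / (length(vidx) / n_jk_blocks))
  r2_sum <- matrix(0, nb, n_jk_blocks)
  pair_cnt <- matrix(0L, nb, n_jk_blocks)
  complete <- !anyNA(panel$calls[si, vidx, drop = FALSE])
  for (ch in unique(panel$variants$chrom[vidx])) {
    sel <- which(panel$variants$chrom[vidx] == ch)
    pos <- panel$variants$pos_cM[vidx[sel]]
    o <- order(pos)
    sel <- sel[o]; pos <- pos[o]
    m <- length(sel)
    if (m < 2) next
    # pair (i, j), j > i, with lo <= pos[j] - pos[i] < hi; a 1e-9 cM
    # tolerance at the lower edges keeps exact-boundary distances in the
    # bins a real-arithmetic reading of [s, s + width) would assign
    eps <- 1e-9
    jmin <- findInterval(pos + lo - eps, pos, left.open = TRUE) + 1L
    jmax <- findInterval(pos + hi - eps, pos, left.open = TRUE)
    cnt <- pmax(jmax - pmax(jmin, seq_len(m) + 1L) + 1L, 0L)
    ii <- rep.int(seq_len(m), cnt)
    jj <- sequence(cnt, from = pmax(jmin, seq_len(m) + 1L))
    if (!length(ii)) next
    d <- pos[jj] - pos[ii]
    g <- panel$calls[si, vidx[sel], drop = FALSE]
    if (complete) {
      xs <- scale(g)
      r2 <- (colSums(xs[, ii, drop = FALSE] * xs[, jj, drop = FALSE]) /
               (n - 1))^2
    } else {
      r2 <- vapply(seq_along(ii), function(q) {
        x <- g[, ii[q]]; y <- g[, jj[q]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
          return(NA_real_)
        stats::cor(x[ok], y[ok])^2
      }, numeric(1))
      drop_na <- is.na(r2)
      ii <- ii[!drop_na]; jj <- jj[!drop_na]; d <- d[!drop_na]
      r2 <- r2[!drop_na]
    }
    blk <- blk_of[sel][ii]
    base_bin <- floor((d - bins$start_cM[1]) / step) + 1L
    for (k in (-1L):k_over) {  # one extra each side guards fp boundary cases
      b <- base_bin - k
      inside <- b >= 1L & b <= nb & d >= bins$start_cM[pmax(b, 1L)] - eps &
        d < bins$end_cM[pmax(b, 1L)] - eps
      if (!any(inside)) next
      key <- (b[inside] - 1L) * n_jk_blocks + (blk[inside] - 1L)
      acc <- rowsum(cbind(r2[inside], 1), group = key)
      cells <- as.integer(rownames(acc))
      at <- cbind(cells %/% n_jk_blocks + 1L, cells %% n_jk_blocks + 1L)
      r2_sum[at] <- r2_sum[at] + acc[, 1]
      pair_cnt[at] <- pair_cnt[at] + as.integer(acc[, 2])
    }
  }
  tot_cnt <- rowSums(pair_cnt)
  bins$mean_r2 <- ifelse(tot_cnt > 0, rowSums(r2_sum) / tot_cnt, NA_real_)
  bins$n_pairs <- tot_cnt
  structure(list(bins = bins, r2_sum = r2_sum, pair_count = pair_cnt,
                 n_samples = n, population = population),
            class = "ld_decay")
}

#' Finite-sample adjustment of mean r-squared
#'
#' Sample LD r-squared is inflated by roughly \code{1/n} for \code{n}
#' sampled diploid individuals; the adjustment subtracts it. Adjusted values
#' at or below zero carry no drift signal and are marked invalid
#' (\code{NA}), which excludes the bin.
#'
#' @param mean_r2 mean r-squared value(s).
#' @param n_samples number of diploid samples used (>= 2).
#' @return adjusted value(s); \code{NA} where invalid.
#' @export
adjust_r2 <- function(mean_r2, n_samples) {
  stopifnot(n_samples >= 2)
  adj <- mean_r2 - 1 / n_samples
  adj[!is.na(adj) & adj <= 0] <- NA_real_
  adj
}

#' Point Ne from one recombination distance and r-squared
#'
#' The drift-recombination equilibrium inversion
#' \deqn{N_e \approx \frac{1}{4c}\left(\frac{1}{r^2} - 2\right)}
#' with \code{c} in Morgans. Values of r-squared above 0.5 would give a
#' negative size; these are reported as 0 and flagged (attribute
#' \code{negative}).
#'
#' @param c_M recombination distance in Morgans (> 0).
#' @param r2 r-squared in (0, 1]; 0 is undefined (bin excluded upstream).
#' @return Ne value(s), with logical attribute \code{negative}.
#' @export
ne_point <- function(c_M, r2) {
  stopifnot(all(c_M > 0))
  raw <- (1 / r2 - 2) / (4 * c_M)
  neg <- !is.na(raw) & raw < 0
  out <- ifelse(neg, 0, raw)
  attr(out, "negative") <- neg
  out
}

#' Ne trajectory from binned LD decay
#'
#' Each valid bin maps to a point in the past: time \eqn{t = 1/(2c)}
#' generations, and \eqn{N_e} from \code{\link{ne_point}} applied to the
#' bin's sample-size-adjusted mean r-squared. 95% confidence intervals come
#' from a weighted delete-one-block jackknife over the contiguous genomic
#' blocks of pairs, propagated through the adjustment and the Ne formula.
#' Bins with no pairs or with adjusted r-squared <= 0 are excluded; bins
#' with r-squared > 0.5 yield Ne = 0 and are flagged.
#'
#' @param ld an \code{ld_decay} object from \code{\link{r2_by_distance}}.
#' @param adjust apply the \code{1/n} sample-size adjustment (default TRUE;
#'   FALSE reproduces the literal equilibrium formula on raw r-squared).
#' @param conf confidence level for the intervals.
#' @return object of class \code{ne_trajectory}: \code{points} data.frame
#'   (\code{start_cM}, \code{mid_cM}, \code{c_M}, \code{t_gen},
#'   \code{mean_r2}, \code{adj_r2}, \code{ne}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{n_pairs}, \code{flag_negative}), plus the
#'   jackknife matrices for long-term propagation.
#' @export
trajectory <- function(ld, adjust = TRUE, conf = 0.95) {
  stopifnot(inherits(ld, "ld_decay"))
  b <- ld$bins
  n <- ld$n_samples
  adj_fun <- if (adjust) function(r) adjust_r2(r, n) else function(r) {
    r[!is.na(r) & r <= 0] <- NA_real_
    r
  }
  adj <- adj_fun(b$mean_r2)
  valid <- !is.na(adj) & b$n_pairs > 0
  ne <- rep(NA_real_, nrow(b))
  neg <- rep(FALSE, nrow(b))
  nv <- ne_point(b$c_M[valid], adj[valid])
  ne[valid] <- nv
  neg[valid] <- attr(nv, "negative")
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  se <- ci_lo <- ci_hi <- rep(NA_real_, nrow(b))
  tot_s <- rowSums(ld$r2_sum)
  tot_c <- rowSums(ld$pair_count)
  for (i in which(valid)) {
    use_blk <- ld$pair_count[i, ] > 0
    g <- sum(use_blk)
    if (g < 2) next
    m_j <- ld$pair_count[i, use_blk]
    r_minus <- (tot_s[i] - ld$r2_sum[i, use_blk]) / (tot_c[i] - m_j)
    a_minus <- adj_fun(r_minus)
    ok <- !is.na(a_minus)
    if (sum(ok) < 2) next
    th_minus <- as.numeric(ne_point(b$c_M[i], a_minus[ok]))
    s <- jackknife_se(ne[i], th_minus, m_j[ok])
    se[i] <- s
    ci_lo[i] <- ne[i] - zq * s
    ci_hi[i] <- ne[i] + zq * s
  }
  pts <- data.frame(start_cM = b$start_cM, mid_cM = b$mid_cM, c_M = b$c_M,
                    t_gen = b$t_gen, mean_r2 = b$mean_r2, adj_r2 = adj,
                    ne = ne, se = se, ci_low = ci_lo, ci_high = ci_hi,
                    n_pairs = b$n_pairs, flag_negative = neg)[valid, ]
  rownames(pts) <- NULL
  structure(list(points = pts, population = ld$population,
                 n_samples = n, adjust = adjust, conf = conf,
                 r2_sum = ld$r2_sum, pair_count = ld$pair_count,
                 bins = b),
            class = "ne_trajectory")
}

# Busing et al. (1999) weighted delete-one jackknife SE around the full
# estimate theta, given delete-one estimates and block weights.
jackknife_se <- function(theta, theta_minus, weights) {
  g <- length(theta_minus)
  n <- sum(weights)
  h <- n / weights
  theta_J <- g * theta - sum((1 - weights / n) * theta_minus)
  pseudo <- h * theta - (h - 1) * theta_minus
  sqrt(sum((pseudo - theta_J)^2 / (h - 1)) / g)
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("ne_trajectory for", x$population, "--", nrow(x$points),
      "valid bins,", x$n_samples, "samples\n")
  if (nrow(x$points)) {
    rng <- range(x$points$t_gen)
    cat(sprintf("time span: %.0f-%.0f generations; Ne range: %.0f-%.0f\n",
                rng[1], rng[2], min(x$points$ne), max(x$points$ne)))
  }
  invisible(x)
}

#' Long-term Ne as the harmonic mean of a trajectory
#'
#' Harmonic mean of the per-bin Ne values (points with Ne <= 0 are excluded
#' and counted); the confidence interval propagates the same delete-one-block
#' jackknife through every bin and the harmonic mean.
#'
#' @param traj an \code{ne_trajectory}.
#' @return list of class \code{long_term_ne}: \code{population},
#'   \code{ne_harmonic}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{n_bins_used}, \code{n_excluded}.
#' @export
long_term_ne <- function(traj) {
  stopifnot(inherits(traj, "ne_trajectory"))
  pts <- traj$points
  use <- pts$ne > 0
  if (!any(use)) stop("no bins with positive Ne")
  hm <- function(x) length(x) / sum(1 / x)
  est <- hm(pts$ne[use])
  # delete-one-block recomputation of the whole trajectory
  n_blk <- ncol(traj$r2_sum)
  adj_fun <- if (traj$adjust) function(r) adjust_r2(r, traj$n_samples)
  else function(r) { r[!is.na(r) & r <= 0] <- NA_real_; r }
  tot_s <- rowSums(traj$r2_sum)
  tot_c <- rowSums(traj$pair_count)
  th_minus <- rep(NA_real_, n_blk)
  w <- colSums(traj$pair_count)
  for (j in seq_len(n_blk)) {
    if (w[j] == 0) next
    cnt <- tot_c - traj$pair_count[, j]
    r_minus <- ifelse(cnt > 0, (tot_s - traj$r2_sum[, j]) / cnt, NA_real_)
    a <- adj_fun(r_minus)
    okb <- !is.na(a)
    if (!any(okb)) next
    nev <- as.numeric(ne_point(traj$bins$c_M[okb], a[okb]))
    nev <- nev[nev > 0]
    if (!length(nev)) next
    th_minus[j] <- hm(nev)
  }
  okj <- !is.na(th_minus)
  se <- if (sum(okj) >= 2) jackknife_se(est, th_minus[okj], w[okj])
  else NA_real_
  zq <- stats::qnorm(1 - (1 - traj$conf) / 2)
  structure(list(population = traj$population, ne_harmonic = est,
                 se = se, ci_low = est - zq * se, ci_high = est + zq * se,
                 n_bins_used = sum(use), n_excluded = sum(!use)),
            class = "long_term_ne")
}

#' @export
print.long_term_ne <- function(x, ...) {
  cat(sprintf("long-term Ne (%s): %.0f [%.0f, %.0f], %d bins (%d excluded)\n",
              x$population, x$ne_harmonic, x$ci_low, x$ci_high,
              x$n_bins_used, x$n_excluded))
  invisible(x)
}

#' Recent-time Ne summary from the largest-distance bins
#'
#' The largest recombination distances correspond to the most recent
#' generations (\eqn{t = 1/(2c)}); their median Ne summarizes recent size.
#'
#' @param traj an \code{ne_trajectory}.
#' @param n_bins number of largest-distance valid bins to summarize.
#' @return median Ne over those bins.
#' @export
recent_ne <- function(traj, n_bins = 25) {
  pts <- traj$points[traj$points$ne > 0, ]
  if (!nrow(pts)) stop("no bins with positive Ne")
  pts <- pts[order(-pts$c_M), ]
  stats::median(pts$ne[seq_len(min(n_bins, nrow(pts)))])
}

#' Divergence time between two populations from FST and Ne
#'
#' Under pure drift after a clean split,
#' \eqn{F_{ST} = 1 - (1 - 1/(2N_e))^T}, inverted as
#' \deqn{T = \ln(1 - F_{ST}) / \ln(1 - 1/(2N_e))}
#' in generations. The pair's Ne is the harmonic mean of the two
#' populations' long-term Ne. Negative FST input (estimator noise) is
#' clipped to 0; FST >= 1 is an error (infinite divergence).
#'
#' @param fst pairwise FST in [0, 1).
#' @param ne_A,ne_B long-term Ne of the two populations
#'   (\code{long_term_ne} objects or plain numbers).
#' @param generation_years years per generation (default 25).
#' @return list of class \code{divergence_result}: \code{fst},
#'   \code{ne_pair}, \code{t_generations}, \code{t_years},
#'   \code{generation_years}.
#' @export
divergence_time <- function(fst, ne_A, ne_B = ne_A, generation_years = 25) {
  get_ne <- function(x) if (inherits(x, "long_term_ne")) x$ne_harmonic
  else as.numeric(x)
  a <- get_ne(ne_A); b <- get_ne(ne_B)
  ne_pair <- 2 / (1 / a + 1 / b)
  if (ne_pair <= 0.5) stop("pair Ne must exceed 0.5")
  if (fst >= 1) stop("fst >= 1 implies infinite divergence")
  fst <- max(fst, 0)
  t_gen <- if (fst == 0) 0 else log(1 - fst) / log(1 - 1 / (2 * ne_pair))
  structure(list(fst = fst, ne_pair = ne_pair, t_generations = t_gen,
                 t_years = t_gen * generation_years,
                 generation_years = generation_years),
            class = "divergence_result")
}

#' Pairwise divergence-time matrix over populations
#'
#' FST is computed for every unordered population pair (zero-clipped for the
#' time formula) and converted to generations and years with
#' \code{\link{divergence_time}}, using per-population long-term Ne values.
#'
#' @param panel a \code{genotype_panel}.
#' @param populations labels; default all in the panel.
#' @param ne per-population long-term Ne: a named numeric vector (or a
#'   single number recycled), or a named list of \code{long_term_ne}
#'   objects.
#' @param estimator FST estimator, see \code{\link{pairwise_fst}}.
#' @param generation_years years per generation.
#' @return list: \code{t_generations} and \code{t_years} (symmetric,
#'   zero-diagonal matrices), \code{fst} (clipped matrix), \code{pairs}
#'   data.frame (\code{popA}, \code{popB}, \code{fst}, \code{ne_pair},
#'   \code{t_generations}, \code{t_years}).
#' @export
divergence_matrix <- function(panel, populations = NULL, ne,
                              estimator = c("wc", "hudson"),
                              generation_years = 25) {
  estimator <- match.arg(estimator)
  if (is.null(populations)) populations <- unique(panel$samples$population)
  k <- length(populations)
  stopifnot(k >= 2)
  if (is.list(ne) && !inherits(ne, "long_term_ne"))
    ne <- vapply(ne, function(x) if (inherits(x, "long_term_ne"))
      x$ne_harmonic else as.numeric(x), numeric(1))
  ne <- if (length(ne) == 1 && is.null(names(ne)))
    stats::setNames(rep(as.numeric(ne), k), populations)
  else {
    if (!all(populations %in% names(ne)))
      stop("ne must be named for every population")
    ne[populations]
  }
  fstm <- fst_matrix(panel, populations, estimator, clipped = TRUE)
  tg <- ty <- matrix(0, k, k, dimnames = list(populations, populations))
  pairs <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- divergence_time(fstm[i, j], ne[[i]], ne[[j]], generation_years)
    tg[i, j] <- tg[j, i] <- d$t_generations
    ty[i, j] <- ty[j, i] <- d$t_years
    pairs <- rbind(pairs, data.frame(
      popA = populations[i], popB = populations[j], fst = fstm[i, j],
      ne_pair = d$ne_pair, t_generations = d$t_generations,
      t_years = d$t_years))
  }
  list(t_generations = tg, t_years = ty, fst = fstm, pairs = pairs)
}
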