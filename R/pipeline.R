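#' Default pipeline configuration
#'
#' All thresholds default to the analysis' canonical parameter set: LD
#' pruning 50-SNP window / 5-SNP step / r2 0.5; inbreeding removal at
#' F >= 0.0156 (second-cousin-offspring level); kinship removal at
#' phi > 0.0884 (second degree); PCA with 10 components and 6-SD outlier
#' flagging; the Ne bin grid 0.005-0.25 cM in 0.001 steps (0.005 width);
#' 25-year generations. An empty override list reproduces this set verbatim.
#'
#' @param ... named overrides of any default.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window_snps = 50, step_snps = 5, r2_max = 0.5,
    F_max = 0.0156, kin_max = 0.0884, exempt_populations = character(),
    pca_k = 10, outlier_sd = 6, outlier_pcs = 10, outlier_iter = 5,
    bin_start = 0.005, bin_stop = 0.25, bin_step = 0.001, bin_width = 0.005,
    ld_maf = 0.1, n_jk_blocks = 20, adjust_r2 = TRUE,
    fst_estimator = "wc", outgroup = NULL,
    generation_years = 25, min_pop_size = 5, seed = 1)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys are config fields.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full population-structure and demography pipeline
#'
#' Stages, in order: QC (LD pruning, inbreeding and kinship filtering, PCA
#' outlier removal), PCA, pairwise FST, optional outgroup-f3 scan, LD-based
#' Ne trajectories and long-term Ne per population, FST-based divergence
#' times, and the UPGMA tree of populations. Every table is written as TSV
#' under \code{out_dir}, the tree as Newick, and a JSON manifest records
#' inputs, parameters and counts. A rerun with the same inputs, config and
#' seed is byte-identical. Ne stages run only when the panel carries genetic
#' positions (annotate with a map first, or pass \code{ne} explicitly).
#'
#' @param panel a \code{genotype_panel} (map-annotated for the Ne stages).
#' @param out_dir output directory (created if needed).
#' @param config a \code{\link{pipeline_config}}.
#' @param ne optional named per-population long-term Ne values; when given,
#'   the LD trajectory stage is skipped and these feed the divergence stage.
#' @return invisibly, a list with the in-memory results of every stage and
#'   \code{files}, the paths written.
#' @export
run_pipeline <- function(panel, out_dir, config = pipeline_config(),
                         ne = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat("", file = log_path)
  files <- character()
  wtsv <- function(x, name, rn = FALSE) {
    p <- file.path(out_dir, name)
    utils::write.table(format(x, digits = 12, trim = TRUE, scientific = FALSE),
                       p, sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
    files[[name]] <<- p
    p
  }
  stage <- "qc"
  res <- list()
  tryCatch({
    logf("stage qc: pruning ", n_variants(panel), " variants")
    kept <- prune_ld(panel, config$window_snps, config$step_snps,
                     config$r2_max)
    pruned <- subset_panel(panel, variants = kept)
    logf("stage qc: ", n_variants(pruned), " variants after LD pruning")
    out_ids <- detect_outliers(pruned, n_sd = config$outlier_sd,
                               n_pcs = min(config$outlier_pcs,
                                           n_samples(pruned) - 2),
                               max_iter = config$outlier_iter)
    filt <- relatedness_filter(pruned, F_max = config$F_max,
                               kin_max = config$kin_max,
                               pca_outliers = out_ids$sample_id,
                               exempt_populations =
                                 config$exempt_populations)
    res$qc <- filt
    res$pruned_variants <- kept
    wtsv(filt$report, "qc_removals.tsv")
    logf("stage qc: removed ", nrow(filt$report), " sample(s); ",
         n_samples(filt$panel), " remain")
    work <- filt$panel

    stage <- "pca"
    pca_k <- min(config$pca_k, n_samples(work) - 1)
    res$pca <- suppressWarnings(compute_pca(work, k = pca_k))
    co <- as.data.frame(res$pca$coordinates)
    co <- cbind(sample = rownames(co),
                population = work$samples$population[
                  match(rownames(co), work$samples$id)], co)
    wtsv(co, "pca_coords.tsv")
    wtsv(data.frame(component = seq_along(res$pca$explained_fraction),
                    eigenvalue = res$pca$eigenvalues[
                      seq_along(res$pca$explained_fraction)],
                    explained_fraction = res$pca$explained_fraction),
         "pca_eigen.tsv")
    logf("stage pca: top-2 explained fraction ",
         sprintf("%.4f", sum(res$pca$explained_fraction[1:2])))

    stage <- "fstats"
    pops <- names(which(table(work$samples$population) >=
                          config$min_pop_size))
    pops <- sort(pops)
    res$fst <- fst_matrix(work, pops, estimator = config$fst_estimator)
    wtsv(as.data.frame(res$fst), "fst_matrix.tsv", rn = TRUE)
    if (!is.null(config$outgroup)) {
      others <- setdiff(pops, config$outgroup)
      res$f3 <- f3_scan(work, config$outgroup, others, others)
      wtsv(res$f3, "f3.tsv")
    }
    logf("stage fstats: ", length(pops), " populations")

    stage <- "ne"
    if (is.null(ne)) {
      if (anyNA(work$variants$pos_cM))
        stop("panel lacks genetic positions; annotate with a map or pass ne")
      bins <- make_bins(config$bin_start, config$bin_stop, config$bin_step,
                        config$bin_width)
      lt <- list()
      for (p in pops) {
        ld <- r2_by_distance(work, p, bins, maf = config$ld_maf,
                             n_jk_blocks = config$n_jk_blocks)
        tr <- trajectory(ld, adjust = config$adjust_r2)
        wtsv(tr$points[, c("t_gen", "ne", "ci_low", "ci_high", "mean_r2",
                           "n_pairs")],
             paste0("ne_trajectory_", p, ".tsv"))
        lt[[p]] <- long_term_ne(tr)
        logf("stage ne: ", p, " long-term Ne ",
             sprintf("%.0f", lt[[p]]$ne_harmonic))
      }
      res$long_term_ne <- lt
      ne_vec <- vapply(lt, `[[`, numeric(1), "ne_harmonic")
      wtsv(data.frame(population = names(lt), ne_harmonic = ne_vec,
                      ci_low = vapply(lt, `[[`, numeric(1), "ci_low"),
                      ci_high = vapply(lt, `[[`, numeric(1), "ci_high")),
           "ne_longterm.tsv")
    } else {
      ne_vec <- ne
      logf("stage ne: using supplied long-term Ne values")
    }

    stage <- "divergence"
    res$divergence <- divergence_matrix(work, pops, ne = ne_vec,
                                        estimator = config$fst_estimator,
                                        generation_years =
                                          config$generation_years)
    wtsv(as.data.frame(res$divergence$t_generations),
         "divergence_matrix.tsv", rn = TRUE)
    wtsv(res$divergence$pairs, "divergence_pairs.tsv")

    stage <- "tree"
    if (length(pops) >= 2) {
      res$tree <- upgma(res$divergence$t_generations)
      for (u in c("generations", "years")) {
        p <- file.path(out_dir, paste0("tree_", u, ".nwk"))
        writeLines(write_newick(res$tree, units = u,
                                generation_years = config$generation_years),
                   p)
        files[[basename(p)]] <- p
      }
      logf("stage tree: ", length(tree_leaves(res$tree)), " leaves")
    }

    stage <- "manifest"
    manifest <- list(
      n_samples_in = n_samples(panel), n_variants_in = n_variants(panel),
      n_samples_kept = n_samples(work),
      n_variants_pruned = length(kept),
      populations = pops,
      parameters = unclass(config),
      outputs = names(files),
      r_version = paste(R.version$major, R.version$minor, sep = "."))
    mp <- file.path(out_dir, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), mp)
    files[["manifest.json"]] <- mp
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res$files <- files
  invisible(res)
}
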