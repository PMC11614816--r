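#' Genetic map container
#'
#' A per-chromosome monotone bp -> cM mapping. Within each chromosome
#' \code{pos_bp} must be strictly increasing and \code{pos_cM} non-decreasing.
#'
#' @param table data.frame with columns \code{chrom}, \code{pos_bp},
#'   \code{pos_cM}.
#' @return an object of class \code{genetic_map} (the validated, sorted table).
#' @export
genetic_map <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos_bp", "pos_cM") %in% names(table)))
  table$chrom <- as.character(table$chrom)
  table <- table[order(table$chrom, table$pos_bp), , drop = FALSE]
  for (ch in unique(table$chrom)) {
    sub <- table[table$chrom == ch, ]
    if (any(diff(sub$pos_bp) <= 0))
      stop("pos_bp not strictly increasing on chromosome ", ch)
    if (any(diff(sub$pos_cM) < 0))
      stop("pos_cM decreasing on chromosome ", ch)
  }
  rownames(table) <- NULL
  structure(table, class = c("genetic_map", "data.frame"))
}

#' Read a genetic map from a whitespace-delimited table
#'
#' Expected columns (with or without a header line): chromosome, base-pair
#' position, centimorgan position.
#'
#' @param path file path.
#' @return a \code{genetic_map}.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\S+\\s+\\d+\\s+[0-9.eE+-]+\\s*$", first)
  tab <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header || !all(c("chrom", "pos_bp", "pos_cM") %in% names(tab)))
    names(tab)[1:3] <- c("chrom", "pos_bp", "pos_cM")
  genetic_map(tab[, c("chrom", "pos_bp", "pos_cM")])
}

#' Annotate variants with genetic (cM) positions
#'
#' Sets \code{pos_cM} by linear interpolation in bp between the flanking map
#' points of the variant's chromosome. Variants outside the mapped range are
#' clamped to the boundary cM value (no extrapolation, so genetic positions
#' can neither go negative nor run away).
#'
#' @param panel a \code{genotype_panel}.
#' @param map a \code{genetic_map} covering every chromosome in the panel.
#' @return the panel with \code{variants$pos_cM} filled.
#' @export
annotate_genetic_positions <- function(panel, map) {
  chroms <- unique(panel$variants$chrom)
  absent <- setdiff(chroms, unique(map$chrom))
  if (length(absent))
    stop("chromosome(s) absent from genetic map: ",
         paste(absent, collapse = ", "))
  cm <- numeric(nrow(panel$variants))
  for (ch in chroms) {
    vi <- panel$variants$chrom == ch
    sub <- map[map$chrom == ch, ]
    cm[vi] <- stats::approx(sub$pos_bp, sub$pos_cM,
                            xout = panel$variants$pos_bp[vi],
                            rule = 2, ties = "ordered")$y
  }
  panel$variants$pos_cM <- cm
  panel
}

#' Read a sample -> population assignment table
#'
#' TSV with columns \code{id}, \code{population} and optional \code{tags}.
#'
#' @param path file path.
#' @return data.frame usable as a panel's \code{samples} slot.
#' @export
read_populations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  stopifnot(all(c("id", "population") %in% names(tab)))
  if (is.null(tab$tags)) tab$tags <- ""
  tab
}

#' Assign populations to a panel's samples
#' @param panel a \code{genotype_panel}.
#' @param populations data.frame as returned by \code{\link{read_populations}}.
#' @return the panel with \code{samples$population} (and tags) replaced.
#' @export
set_populations <- function(panel, populations) {
  m <- match(panel$samples$id, populations$id)
  if (anyNA(m))
    stop("samples missing from population table: ",
         paste(panel$samples$id[is.na(m)], collapse = ", "))
  panel$samples$population <- populations$population[m]
  if (!is.null(populations$tags)) panel$samples$tags <- populations$tags[m]
  panel
}

# ---- PLINK bed/bim/fam ------------------------------------------------------

# PLINK 1 binary: magic 0x6c 0x1b, mode byte 0x01 = SNP-major. Each variant is
# ceil(n/4) bytes; 2-bit codes per sample: 00=hom A1, 01=missing, 10=het,
# 11=hom A2. bim column A1 is taken as the alt allele (dosage-counted), A2 as
# ref, matching PLINK's minor/major convention on write.

#' Read a PLINK bed/bim/fam fileset into a genotype panel
#'
#' @param bed_path,bim_path,fam_path paths; \code{bim}/\code{fam} default to
#'   the bed path with swapped extensions.
#' @return a \code{genotype_panel}. The bim A1 allele is the counted (alt)
#'   allele; the fam FID is used as the population label.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  bim <- utils::read.table(bim_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "pos_cM", "pos_bp",
                                         "a1", "a2"))
  fam <- utils::read.table(fam_path, header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_var <- ceiling(n / 4)
  raw <- readBin(bed_path, "raw", n = 3 + m * bytes_per_var + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files are supported: ", bed_path)
  if (length(raw) != 3 + m * bytes_per_var)
    stop("bed payload is ", length(raw) - 3, " bytes; expected ",
         m * bytes_per_var, " for ", n, " samples x ", m,
         " variants (dimension mismatch)")
  body <- as.integer(raw[-(1:3)])
  # decode the four 2-bit fields of every byte at once
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  # bed code -> dosage of A1 (alt): 00->2, 10->1, 11->0, 01->missing
  lookup <- c(2L, NA_integer_, 1L, 0L)
  geno <- matrix(lookup[codes + 1L], nrow = 4 * bytes_per_var)
  calls <- geno[seq_len(n), , drop = FALSE]
  bad <- which(bim$a1 == bim$a2)
  if (length(bad))
    stop("non-biallelic bim row (A1 == A2): ",
         paste(bim$id[bad], collapse = ", "))
  variants <- data.frame(chrom = as.character(bim$chrom),
                         pos_bp = bim$pos_bp, id = bim$id,
                         ref = bim$a2, alt = bim$a1,
                         pos_cM = ifelse(bim$pos_cM == 0, NA_real_,
                                         bim$pos_cM))
  samples <- data.frame(id = as.character(fam[[2]]),
                        population = as.character(fam[[1]]))
  genotype_panel(calls, variants, samples)
}

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' @param panel a \code{genotype_panel}.
#' @param prefix output path prefix; \code{.bed/.bim/.fam} are appended.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- n_samples(panel)
  m <- n_variants(panel)
  v <- panel$variants
  cm <- ifelse(is.na(v$pos_cM), 0, v$pos_cM)
  utils::write.table(
    data.frame(v$chrom, v$id, cm, v$pos_bp, v$alt, v$ref),
    paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  s <- panel$samples
  utils::write.table(
    data.frame(s$population, s$id, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(1L, nrow = n, ncol = m)
  ok <- !is.na(panel$calls)
  code[ok] <- c(3L, 2L, 0L)[panel$calls[ok] + 1L]
  bytes_per_var <- ceiling(n / 4)
  pad <- 4 * bytes_per_var - n
  if (pad) code <- rbind(code, matrix(0L, nrow = pad, ncol = m))
  w <- c(1L, 4L, 16L, 64L)
  idx <- rep(seq_len(bytes_per_var), each = 4)
  packed <- rowsum(code * w, group = rep(idx, m)[seq_len(4 * bytes_per_var)],
                   reorder = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}

# ---- VCF --------------------------------------------------------------------

#' Read a VCF into a genotype panel
#'
#' Diploid GT fields are decoded to alt-allele dosage (0/0 -> 0, 0/1 or
#' 1/0 -> 1, 1/1 -> 2, ./. -> missing; phased separators accepted).
#' Multi-allelic records and records with haploid or otherwise malformed GT
#' are skipped; the skip count is reported as an attribute and a message.
#'
#' @param vcf_path path to an (optionally gzipped) VCF with a GT field.
#' @return a \code{genotype_panel} with attribute \code{n_skipped}.
#' @export
read_vcf <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  gt_chr <- sub("\\|", "/", gt)
  gt_chr[is.na(gt_chr)] <- "./."
  ok_tokens <- gt_chr %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  malformed <- rowSums(matrix(!ok_tokens, nrow = nrow(gt))) > 0
  skip <- multi | malformed
  n_skipped <- sum(skip)
  if (n_skipped)
    message("read_vcf: skipped ", n_skipped,
            " record(s) (multi-allelic or malformed GT)")
  fix <- fix[!skip, , drop = FALSE]
  gt_chr <- gt_chr[!skip, , drop = FALSE]
  dosage <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "./." = NA_integer_)
  calls <- t(matrix(dosage[gt_chr], nrow = nrow(gt_chr)))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  variants <- data.frame(chrom = fix$CHROM, pos_bp = as.integer(fix$POS),
                         id = ids, ref = fix$REF, alt = fix$ALT)
  samples <- data.frame(id = colnames(gt_chr), population = "unknown")
  panel <- genotype_panel(calls, variants, samples)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a genotype panel as a minimal VCF v4.2
#'
#' @param panel a \code{genotype_panel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$id),
                     collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  g <- matrix("./.", nrow = n_samples(panel), ncol = n_variants(panel))
  ok <- !is.na(panel$calls)
  g[ok] <- gt_str[panel$calls[ok] + 1L]
  v <- panel$variants
  lines <- paste(v$chrom, v$pos_bp, v$id, v$ref, v$alt, ".", "PASS", ".",
                 "GT", apply(g, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# ---- merging ----------------------------------------------------------------

#' Merge genotype panels on their shared variants
#'
#' Variants are matched across panels on (chrom, pos_bp). At a shared site the
#' allele pairs must either match exactly or be a ref/alt swap; the merged
#' variant is stored in a canonical orientation (alt = lexicographically
#' smaller allele) and any panel oriented the other way has its dosages
#' flipped d -> 2 - d, so the merge is symmetric in panel order.
#' Irreconcilable allele pairs -- including strand-ambiguous A/T and C/G
#' mismatches, whose orientation cannot be established -- are dropped and
#' counted. Samples are concatenated and must be globally unique.
#'
#' @param panels list of two or more \code{genotype_panel}s.
#' @return merged \code{genotype_panel} with attribute \code{n_dropped}
#'   (variants shared by position but allele-irreconcilable).
#' @export
merge_panels <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 2)
  ids <- unlist(lapply(panels, function(p) p$samples$id))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) across panels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keys <- lapply(panels, function(p)
    paste(p$variants$chrom, p$variants$pos_bp, sep = ":"))
  shared <- sort(Reduce(intersect, keys))
  i1 <- match(shared, keys[[1]])
  canon <- panels[[1]]$variants[i1, , drop = FALSE]
  flip1 <- canon$alt > canon$ref
  tmp <- canon$alt[flip1]
  canon$alt[flip1] <- canon$ref[flip1]
  canon$ref[flip1] <- tmp
  keep <- rep(TRUE, length(shared))
  blocks <- vector("list", length(panels))
  for (k in seq_along(panels)) {
    ik <- match(shared, keys[[k]])
    vk <- panels[[k]]$variants[ik, , drop = FALSE]
    same <- vk$ref == canon$ref & vk$alt == canon$alt
    swap <- vk$ref == canon$alt & vk$alt == canon$ref
    keep <- keep & (same | swap)
    g <- panels[[k]]$calls[, ik, drop = FALSE]
    if (any(swap)) g[, swap] <- 2L - g[, swap, drop = FALSE]
    blocks[[k]] <- g
  }
  n_dropped <- sum(!keep)
  if (n_dropped)
    message("merge_panels: dropped ", n_dropped,
            " variant(s) with irreconcilable alleles")
  calls <- do.call(rbind, lapply(blocks, function(b)
    b[, keep, drop = FALSE]))
  samples <- do.call(rbind, lapply(panels, function(p)
    p$samples[, c("id", "population", "tags")]))
  out <- genotype_panel(calls, canon[keep, , drop = FALSE], samples)
  attr(out, "n_dropped") <- n_dropped
  out
}
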