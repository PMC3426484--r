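#' SNPs falling in a gene region (gene body plus flanks)
#'
#' The region is `[tx_start - flank_bp, tx_end + flank_bp]`, both bounds
#' inclusive, on the gene's chromosome.
#'
#' @param gene a `gene_id` present in `catalog`
#' @param catalog a [gene_catalog()]
#' @param panel a [haplotype_panel()] (only its SNP table is used); a
#'   `snp_score_track` also works
#' @param flank_bp flank size in bp (default 100000, the study window)
#' @return integer vector of SNP row indices (possibly empty).
#' @export
assemble_region <- function(gene, catalog, panel, flank_bp = 100000) {
  row <- catalog[catalog$gene_id == gene, ]
  if (nrow(row) != 1) stop("gene not in catalog: ", gene)
  snps <- if (inherits(panel, "haplotype_panel")) panel$snps else panel
  which(snps$chromosome == row$chromosome &
          snps$position_bp >= row$tx_start - flank_bp &
          snps$position_bp <= row$tx_end + flank_bp)
}

#' Fisher's combination of SNP p-values
#'
#' `Z_F = -2 sum(ln p_i)`, distributed as chi-square with `2k` degrees of
#' freedom under the null of k independent uniform p-values; `p_fisher`
#' is the upper tail at `Z_F`.
#'
#' @param p_values vector of p-values in (0, 1]
#' @return list with `z_fisher`, `k`, `p_fisher`; `NULL` for empty input
#'   (the gene is unscored).
#' @export
fisher_combine <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) return(NULL)
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  k <- length(p_values)
  z <- -2 * sum(log(p_values))
  list(z_fisher = z, k = k,
       p_fisher = stats::pchisq(z, df = 2 * k, lower.tail = FALSE))
}

#' Gene-level Fisher scan over all tracks
#'
#' For every gene and every group x statistic track, combines the
#' empirical p-values of the SNPs in the gene region (gene body plus
#' `flank_bp`) into `z_fisher` / `p_fisher`. Genes whose region holds no
#' scored SNP are reported unscored (`k = 0`, missing scores), not as
#' errors. Genes with overlapping flanks score their shared SNPs
#' independently.
#'
#' @param tracks a `snp_score_track` (possibly row-bound over groups and
#'   statistics) carrying an `emp_p` column from [empirical_p()]
#' @param catalog a [gene_catalog()]
#' @param flank_bp flank in bp (default 100000)
#' @return data frame of class `gene_region_result`: one row per gene x
#'   group x statistic with `gene_id`, `group`, `statistic`, `k`,
#'   `z_fisher`, `p_fisher`.
#' @export
gene_scan <- function(tracks, catalog, flank_bp = 100000) {
  stopifnot("emp_p" %in% names(tracks))
  combos <- unique(tracks[, c("group", "statistic")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- tracks[tracks$group == combos$group[i] &
                   tracks$statistic == combos$statistic[i], ]
    for (g in catalog$gene_id) {
      idx <- assemble_region(g, catalog, tr, flank_bp)
      fc <- fisher_combine(tr$emp_p[idx])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, group = combos$group[i],
        statistic = combos$statistic[i],
        k = if (is.null(fc)) 0L else fc$k,
        z_fisher = if (is.null(fc)) NA_real_ else fc$z_fisher,
        p_fisher = if (is.null(fc)) NA_real_ else fc$p_fisher,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gene_region_result", "data.frame")
  res
}

#' Gene-level scan of the genomic background regions
#'
#' Applies the same Fisher pipeline to a catalog of background regions,
#' yielding the null distribution of `p_fisher` per group x statistic.
#' Background regions (including flanks) must be pairwise non-overlapping
#' and are expected to be disjoint from the pathway genes.
#'
#' @param background_catalog a [gene_catalog()] of background regions
#' @param tracks as in [gene_scan()]
#' @param flank_bp flank in bp
#' @return a `gene_region_result` data frame for the background regions.
#' @export
background_scan <- function(background_catalog, tracks, flank_bp = 100000) {
  bc <- background_catalog[order(background_catalog$chromosome,
                                 background_catalog$tx_start), ]
  for (chr in unique(bc$chromosome)) {
    b <- bc[bc$chromosome == chr, ]
    if (nrow(b) > 1) {
      lo <- b$tx_start - flank_bp
      hi <- b$tx_end + flank_bp
      if (any(lo[-1] <= hi[-nrow(b)]))
        stop("background regions overlap on ", chr)
    }
  }
  gene_scan(tracks, background_catalog, flank_bp)
}

#' Bonferroni correction over groups and methods
#'
#' `min(1, p * n_groups * n_methods)`; with the study defaults of 7
#' continental groups and 2 statistics the multiplier is 14.
#'
#' @param p p-values in (0, 1]
#' @param n_groups number of continental groups (default 7)
#' @param n_methods number of statistics combined (default 2)
#' @return corrected p-values, capped at 1.
#' @export
bonferroni_correct <- function(p, n_groups = 7L, n_methods = 2L) {
  pmin(1, p * n_groups * n_methods)
}

#' Empirical gene significance against the background distribution
#'
#' Each gene's `p_fisher` is ranked against the matching group x
#' statistic background distribution:
#' `emp_rank_p = (#\{background <= gene\} + 1) / (N_bg + 1)`. A gene is
#' called significant when its empirical rank p is at or below
#' `alpha / (n_groups * n_methods)` (inclusive), i.e. it belongs to the
#' alpha tail of the genomic distribution after Bonferroni correction.
#' `corrected_p` is the Bonferroni-corrected `p_fisher` (the quantity the
#' study tables print).
#'
#' @param results a `gene_region_result` from [gene_scan()]
#' @param background a `gene_region_result` from [background_scan()]
#' @param alpha empirical significance level (default 0.05)
#' @param n_groups number of groups; default: number of distinct groups
#'   in `results`
#' @param n_methods number of statistics (default: distinct statistics in
#'   `results`)
#' @return `results` with added columns `emp_rank_p`, `corrected_p`,
#'   `significant`.
#' @export
empirical_gene_significance <- function(results, background, alpha = 0.05,
                                        n_groups = NULL, n_methods = NULL) {
  if (nrow(background) == 0 || all(is.na(background$p_fisher)))
    stop("background distribution is empty")
  if (is.null(n_groups)) n_groups <- length(unique(results$group))
  if (is.null(n_methods)) n_methods <- length(unique(results$statistic))
  threshold <- alpha / (n_groups * n_methods)
  results$emp_rank_p <- NA_real_
  for (g in unique(results$group)) {
    for (s in unique(results$statistic)) {
      bg <- background$p_fisher[background$group == g &
                                  background$statistic == s]
      bg <- bg[!is.na(bg)]
      if (length(bg) == 0) next
      idx <- which(results$group == g & results$statistic == s &
                     !is.na(results$p_fisher))
      results$emp_rank_p[idx] <- vapply(results$p_fisher[idx], function(p)
        (sum(bg <= p) + 1) / (length(bg) + 1), numeric(1))
    }
  }
  results$corrected_p <- bonferroni_correct(results$p_fisher,
                                            n_groups, n_methods)
  results$significant <- !is.na(results$emp_rank_p) &
    results$emp_rank_p <= threshold
  attr(results, "alpha") <- alpha
  attr(results, "threshold") <- threshold
  results
}
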