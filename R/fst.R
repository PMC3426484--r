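#' Haplotype allele counts for one group versus the rest
#'
#' Counts are over haplotypes (the panel is phased), not individuals;
#' missing codes are excluded from both the totals and the derived counts.
#'
#' @param panel a [haplotype_panel()]
#' @param scheme a [group_scheme()]
#' @param group focal group label
#' @return data frame with one row per SNP: `snp_id`, `n_focal`,
#'   `derived_focal`, `n_rest`, `derived_rest`.
#' @export
group_allele_counts <- function(panel, scheme, group) {
  rows <- group_hap_rows(panel, scheme, group)
  h <- panel$haplotypes
  hf <- h[rows, , drop = FALSE]
  hr <- h[-rows, , drop = FALSE]
  data.frame(snp_id = panel$snps$snp_id,
             n_focal = colSums(!is.na(hf)),
             derived_focal = colSums(hf, na.rm = TRUE),
             n_rest = colSums(!is.na(hr)),
             derived_rest = colSums(hr, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' Per-SNP two-population F_ST
#'
#' Three estimators are available, all operating on haploid (haplotype)
#' allele counts for the focal group versus the pooled rest:
#' \describe{
#'   \item{weir_cockerham}{the Weir-Cockerham (1984) variance-component
#'     estimator theta-hat specialized to haploid counts in two
#'     subpopulations, `(MSP - MSG) / (MSP + (nc - 1) MSG)`.}
#'   \item{nei_gst}{`(H_T - H_S)/H_T` with `H = 2p(1-p)` and `H_S` the
#'     count-weighted average of within-subpopulation heterozygosities.}
#'   \item{hudson}{`1 - H_w/H_b` in the unbiased form
#'     `((p1-p2)^2 - p1 q1/(n1-1) - p2 q2/(n2-1)) / (p1 q2 + p2 q1)`.}
#' }
#' Sites monomorphic over the pooled sample get `NA`; sites with fewer
#' than 2 haplotypes in either subsample get `NA` with a warning.
#' Negative estimates are clamped to 0 when `clamp = TRUE` (default), so
#' downstream empirical p-values are monotone in differentiation.
#'
#' @param counts data frame as returned by [group_allele_counts()]
#' @param estimator one of `"weir_cockerham"`, `"nei_gst"`, `"hudson"`
#' @param clamp clamp negative estimates to 0 (default `TRUE`)
#' @return numeric vector of F_ST values in `[0, 1]` (or `NA`).
#' @export
fst_snp <- function(counts, estimator = c("weir_cockerham", "nei_gst", "hudson"),
                    clamp = TRUE) {
  estimator <- match.arg(estimator)
  n1 <- counts$n_focal; d1 <- counts$derived_focal
  n2 <- counts$n_rest;  d2 <- counts$derived_rest
  small <- n1 < 2 | n2 < 2
  if (any(small))
    warning(sum(small), " SNP(s) with fewer than 2 haplotypes in a subsample")
  p1 <- d1 / n1
  p2 <- d2 / n2
  nt <- n1 + n2
  pbar <- (d1 + d2) / nt
  mono <- pbar <= 0 | pbar >= 1

  val <- switch(estimator,
    weir_cockerham = {
      msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
      msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nt - 2)
      nc <- nt - (n1^2 + n2^2) / nt
      (msp - msg) / (msp + (nc - 1) * msg)
    },
    nei_gst = {
      ht <- 2 * pbar * (1 - pbar)
      hs <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / nt
      (ht - hs) / ht
    },
    hudson = {
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      num / den
    })
  val[mono | small] <- NA_real_
  if (clamp) val <- pmin(pmax(val, 0), 1)
  val
}

#' Per-SNP F_ST scan, one track per continental group
#'
#' For each group the focal-versus-rest F_ST is computed at every SNP;
#' SNPs whose within-group MAF falls below `per_group_maf` are reported
#' with a missing value (the global MAF filter is assumed to have been
#' applied to the panel already).
#'
#' @param panel a MAF-filtered [haplotype_panel()]
#' @param scheme a [group_scheme()]
#' @param estimator passed to [fst_snp()]
#' @param per_group_maf within-group MAF threshold (default 0.05); set to
#'   0 to disable
#' @param clamp passed to [fst_snp()]
#' @return a `snp_score_track` data frame (one row per SNP x group) with
#'   columns `snp_id`, `chromosome`, `position_bp`, `statistic`, `group`,
#'   `value`, `maf_global`, `maf_group`, `derived_freq_group`.
#' @export
fst_scan <- function(panel, scheme, estimator = "weir_cockerham",
                     per_group_maf = 0.05, clamp = TRUE) {
  maf_global <- panel_maf(panel)
  tracks <- lapply(scheme$groups, function(g) {
    rows <- group_hap_rows(panel, scheme, g)
    counts <- group_allele_counts(panel, scheme, g)
    value <- fst_snp(counts, estimator, clamp = clamp)
    p_grp <- derived_freq(panel, rows)
    maf_grp <- pmin(p_grp, 1 - p_grp)
    if (per_group_maf > 0)
      value[is.na(maf_grp) | maf_grp < per_group_maf] <- NA_real_
    data.frame(snp_id = panel$snps$snp_id,
               chromosome = panel$snps$chromosome,
               position_bp = panel$snps$position_bp,
               statistic = "FST", group = g, value = value,
               maf_global = maf_global, maf_group = maf_grp,
               derived_freq_group = p_grp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  class(out) <- c("snp_score_track", "data.frame")
  out
}
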