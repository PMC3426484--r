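#' Parameters of the iHS scan
#'
#' @param cutoff EHH level at which integration stops (default 0.05, the
#'   usual scan convention)
#' @param n_bins number of equal-width derived-allele-frequency bins used
#'   to standardize unstandardized scores (default 20, width 0.05)
#' @param min_bin_count bins with fewer scored SNPs are merged with their
#'   nearest occupied neighbor (default 10)
#' @param freq_range derived-frequency interval outside which SNPs are not
#'   scored (default `c(0.05, 0.95)`; integrals are unstable outside it)
#' @param boundary `"exclude"` drops SNPs whose EHH has not decayed below
#'   `cutoff` at a chromosome end (`qc_flag = "edge"`); `"keep"` truncates
#'   the integral at the end and keeps the SNP
#' @param distance_mode `"bp"` (physical) or `"cM"` (needs a
#'   `genetic_pos_cM` column in the panel's SNP table)
#' @return a list of class `ihs_params`.
#' @export
ihs_params <- function(cutoff = 0.05, n_bins = 20L, min_bin_count = 10L,
                       freq_range = c(0.05, 0.95),
                       boundary = c("exclude", "keep"),
                       distance_mode = c("bp", "cM")) {
  structure(list(cutoff = cutoff, n_bins = as.integer(n_bins),
                 min_bin_count = as.integer(min_bin_count),
                 freq_range = freq_range,
                 boundary = match.arg(boundary),
                 distance_mode = match.arg(distance_mode)),
            class = "ihs_params")
}

# One-directional EHH walk over a 0/1 haplotype matrix.
# Maintains a partition of the carriers into distinct haplotype classes,
# refined column by column; EHH = sum_h C(n_h,2) / C(n,2).
ehh_walk <- function(hap, carriers, core_idx, positions, step, cutoff,
                     gpos = NULL) {
  n <- length(carriers)
  denom <- n * (n - 1) / 2
  ids <- rep(1L, n)
  m <- ncol(hap)
  cap <- abs((if (step > 0) m else 1L) - core_idx) + 1L
  pts_pos <- numeric(cap); pts_ehh <- numeric(cap)
  pts_g <- if (!is.null(gpos)) numeric(cap) else NULL
  pts_pos[1L] <- positions[core_idx]; pts_ehh[1L] <- 1
  if (!is.null(gpos)) pts_g[1L] <- gpos[core_idx]
  k <- 1L
  j <- core_idx + step
  reached <- FALSE
  while (j >= 1L && j <= m) {
    a <- hap[carriers, j]
    key <- ids * 2L + a
    ids <- match(key, unique(key))
    tab <- tabulate(ids)
    e <- sum(tab * (tab - 1) / 2) / denom
    k <- k + 1L
    pts_pos[k] <- positions[j]; pts_ehh[k] <- e
    if (!is.null(gpos)) pts_g[k] <- gpos[j]
    if (e < cutoff) { reached <- TRUE; break }
    j <- j + step
  }
  out <- data.frame(position_bp = pts_pos[seq_len(k)],
                    ehh = pts_ehh[seq_len(k)])
  if (!is.null(gpos)) out$genetic_pos_cM <- pts_g[seq_len(k)]
  list(points = out, reached_cutoff = reached)
}

#' Extended haplotype homozygosity curve around a core SNP
#'
#' EHH at position x is the probability that two randomly chosen distinct
#' carriers of the core allele are identical over the span from the core
#' to x; it equals 1 at the core and is non-increasing with distance. The
#' curve is truncated at the first point where EHH falls below `cutoff`
#' (that point is included).
#'
#' @param panel a [haplotype_panel()], missing-free at the involved sites
#'   (subset it to one continental group first for a per-group curve)
#' @param core core SNP: `snp_id` or column index
#' @param allele `"ancestral"` (code 0) or `"derived"` (code 1)
#' @param direction `"left"` or `"right"`
#' @param cutoff truncation level (default 0.05)
#' @return an object of class `ehh_curve`: list with `core_snp_id`,
#'   `core_position`, `allele`, `direction`, `points` (data frame
#'   `position_bp`, `ehh`), `reached_cutoff`, `n_carriers`.
#' @export
ehh <- function(panel, core, allele = c("derived", "ancestral"),
                direction = c("right", "left"), cutoff = 0.05) {
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  core_idx <- if (is.character(core)) match(core, panel$snps$snp_id)
              else as.integer(core)
  if (is.na(core_idx) || core_idx < 1 || core_idx > n_snps(panel))
    stop("core SNP not found in panel")
  code <- if (allele == "derived") 1L else 0L
  col <- panel$haplotypes[, core_idx]
  if (anyNA(col)) stop("missing genotypes at the core SNP")
  carriers <- which(col == code)
  if (length(carriers) < 2)
    stop("allele too rare for EHH (", length(carriers), " carrier(s))")
  gpos <- if ("genetic_pos_cM" %in% names(panel$snps))
    panel$snps$genetic_pos_cM else NULL
  w <- ehh_walk(panel$haplotypes, carriers, core_idx, panel$snps$position_bp,
                if (direction == "right") 1L else -1L, cutoff, gpos)
  structure(list(core_snp_id = panel$snps$snp_id[core_idx],
                 core_position = panel$snps$position_bp[core_idx],
                 allele = allele, direction = direction,
                 points = w$points, reached_cutoff = w$reached_cutoff,
                 n_carriers = length(carriers)),
            class = "ehh_curve")
}

# trapezoidal integral of y against x
.trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# integral of one EHH curve against distance from its core
.side_integral <- function(curve, distance_mode = "bp") {
  pts <- curve$points
  if (distance_mode == "cM") {
    if (is.null(pts$genetic_pos_cM))
      stop("distance_mode 'cM' needs a genetic_pos_cM column in the panel")
    x <- abs(pts$genetic_pos_cM - pts$genetic_pos_cM[1])
  } else {
    x <- abs(pts$position_bp - curve$core_position)
  }
  .trapz(x, pts$ehh)
}

#' Integrated EHH (iHH) from a left and a right curve
#'
#' Trapezoidal integral of EHH against distance from the core, each side
#' integrated out to its cutoff truncation, summed over both directions.
#' A side whose EHH never fell below the cutoff before the chromosome end
#' is flagged (`edge = TRUE`); the boundary policy of the scan decides
#' what to do with such SNPs.
#'
#' @param curve_left,curve_right [ehh()] curves sharing the same core
#' @param distance_mode `"bp"` or `"cM"`
#' @return list with `ihh` (the integral) and `edge` (logical).
#' @export
ihh <- function(curve_left, curve_right, distance_mode = c("bp", "cM")) {
  distance_mode <- match.arg(distance_mode)
  if (!identical(curve_left$core_snp_id, curve_right$core_snp_id))
    stop("curves do not share a core SNP")
  value <- .side_integral(curve_left, distance_mode) +
    .side_integral(curve_right, distance_mode)
  list(ihh = value,
       edge = !(curve_left$reached_cutoff && curve_right$reached_cutoff))
}

#' Unstandardized iHS
#'
#' `ln(iHH_ancestral / iHH_derived)`: positive when ancestral haplotypes
#' are longer, negative under a recent sweep on the derived allele.
#'
#' @param ihh_ancestral,ihh_derived integrated EHH values (> 0)
#' @return log ratio, or `NA` if either integral is non-positive.
#' @export
ihs_unstandardized <- function(ihh_ancestral, ihh_derived) {
  out <- rep(NA_real_, length(ihh_ancestral))
  ok <- !is.na(ihh_ancestral) & !is.na(ihh_derived) &
    ihh_ancestral > 0 & ihh_derived > 0
  out[ok] <- log(ihh_ancestral[ok] / ihh_derived[ok])
  out
}

# merge occupied frequency bins below min_count into nearest neighbours;
# returns a vector mapping each raw bin id to a merged bin id
.merge_bins <- function(raw_bin, n_bins, min_count) {
  counts <- tabulate(raw_bin, nbins = n_bins)
  occupied <- which(counts > 0)
  groups <- as.list(occupied)          # each element: raw bins in one group
  repeat {
    sizes <- vapply(groups, function(g) sum(counts[g]), numeric(1))
    if (length(groups) <= 1 || all(sizes >= min_count)) break
    i <- which(sizes < min_count)[which.min(sizes[sizes < min_count])]
    centers <- vapply(groups, function(g) mean(g), numeric(1))
    others <- setdiff(seq_along(groups), i)
    j <- others[which.min(abs(centers[others] - centers[i]))]
    groups[[min(i, j)]] <- sort(c(groups[[i]], groups[[j]]))
    groups[[max(i, j)]] <- NULL
  }
  map <- integer(n_bins)
  for (k in seq_along(groups)) map[groups[[k]]] <- k
  map
}

#' Standardize unstandardized iHS within derived-frequency bins
#'
#' Scored SNPs are binned by derived-allele frequency into `n_bins`
#' equal-width bins; bins with fewer than `min_bin_count` SNPs are merged
#' with their nearest occupied neighbor. Within each (merged) bin the
#' standardized score is `(unstd - bin mean) / bin sd`, so each bin has
#' mean 0 and sd 1 by construction; absolute values are populated.
#'
#' @param results data frame with columns `derived_freq` and
#'   `unstandardized` (`NA` rows pass through unscored)
#' @param n_bins number of equal-width bins over `[0, 1]`
#' @param min_bin_count minimum SNPs per bin before merging
#' @return `results` with added columns `freq_bin`, `standardized`,
#'   `abs_standardized`.
#' @export
standardize_ihs <- function(results, n_bins = 20L, min_bin_count = 10L) {
  stopifnot(all(c("derived_freq", "unstandardized") %in% names(results)))
  scored <- which(!is.na(results$unstandardized))
  results$freq_bin <- NA_integer_
  results$standardized <- NA_real_
  if (length(scored) == 0) {
    results$abs_standardized <- NA_real_
    return(results)
  }
  raw <- pmin(pmax(floor(results$derived_freq[scored] * n_bins) + 1L, 1L),
              n_bins)
  map <- .merge_bins(raw, n_bins, min_bin_count)
  bin <- map[raw]
  std <- rep(NA_real_, length(scored))
  for (b in unique(bin)) {
    idx <- bin == b
    x <- results$unstandardized[scored][idx]
    if (length(x) < 2 || stats::sd(x) == 0)
      stop("degenerate frequency bin with zero variance; cannot standardize")
    std[idx] <- (x - mean(x)) / stats::sd(x)
  }
  results$freq_bin[scored] <- bin
  results$standardized[scored] <- std
  results$abs_standardized <- abs(results$standardized)
  results
}

#' iHS scan of one continental group
#'
#' Full per-SNP pipeline: EHH curves for both alleles in both directions,
#' integrated to iHH, the unstandardized log ratio
#' `ln(iHH_A / iHH_D)`, standardization within derived-frequency bins,
#' and absolute values. SNPs failing QC (allele too rare, frequency
#' outside `freq_range`, zero integral, or chromosome-edge truncation
#' under the `"exclude"` boundary policy) are reported with missing
#' values and a `qc_flag`. Requires an ancestral-oriented, missing-free
#' panel.
#'
#' @param panel a MAF-filtered [haplotype_panel()]
#' @param scheme optional [group_scheme()]; with `group`, restricts the
#'   scan to that group's haplotypes
#' @param group group label (required if `scheme` given)
#' @param params an [ihs_params()]
#' @return a `snp_score_track` data frame (statistic `"ABS_IHS"`) with
#'   columns `snp_id`, `chromosome`, `position_bp`, `statistic`, `group`,
#'   `value` (|standardized iHS|), `maf_global`, `maf_group`,
#'   `derived_freq_group`, `ihh_a`, `ihh_d`, `ihs_unstd`, `ihs` (signed
#'   standardized), `freq_bin`, `qc_flag`.
#' @export
ihs_scan <- function(panel, scheme = NULL, group = NULL,
                     params = ihs_params()) {
  maf_global <- panel_maf(panel)
  sub <- panel
  if (!is.null(scheme)) {
    if (is.null(group)) stop("give a group with the scheme")
    rows <- group_hap_rows(panel, scheme, group)
    sub <- subset_samples(panel, unique((rows + 1L) %/% 2L))
  } else {
    group <- "all"
  }
  if (anyNA(sub$haplotypes))
    stop("iHS requires a missing-free panel (complete haplotypes only)")
  hap <- sub$haplotypes
  pos <- sub$snps$position_bp
  gpos <- if (params$distance_mode == "cM") sub$snps$genetic_pos_cM else NULL
  if (params$distance_mode == "cM" && is.null(gpos))
    stop("distance_mode 'cM' needs a genetic_pos_cM column")
  m <- ncol(hap)
  p_grp <- colMeans(hap)
  ihh_a <- rep(NA_real_, m)
  ihh_d <- rep(NA_real_, m)
  qc <- rep("ok", m)
  lo <- params$freq_range[1]; hi <- params$freq_range[2]

  for (j in seq_len(m)) {
    pj <- p_grp[j]
    if (pj < lo || pj > hi) { qc[j] <- "maf_range"; next }
    der <- which(hap[, j] == 1L)
    anc <- which(hap[, j] == 0L)
    if (length(der) < 2 || length(anc) < 2) { qc[j] <- "too_rare"; next }
    edge <- FALSE
    integrals <- numeric(2)
    for (k in 1:2) {
      carriers <- if (k == 1) anc else der
      wl <- ehh_walk(hap, carriers, j, pos, -1L, params$cutoff, gpos)
      wr <- ehh_walk(hap, carriers, j, pos, 1L, params$cutoff, gpos)
      edge <- edge || !(wl$reached_cutoff && wr$reached_cutoff)
      xs_l <- if (params$distance_mode == "cM")
        abs(wl$points$genetic_pos_cM - wl$points$genetic_pos_cM[1])
        else abs(wl$points$position_bp - pos[j])
      xs_r <- if (params$distance_mode == "cM")
        abs(wr$points$genetic_pos_cM - wr$points$genetic_pos_cM[1])
        else abs(wr$points$position_bp - pos[j])
      integrals[k] <- .trapz(xs_l, wl$points$ehh) + .trapz(xs_r, wr$points$ehh)
    }
    if (edge && params$boundary == "exclude") { qc[j] <- "edge"; next }
    if (any(integrals <= 0)) { qc[j] <- "zero_ihh"; next }
    ihh_a[j] <- integrals[1]
    ihh_d[j] <- integrals[2]
  }

  res <- data.frame(derived_freq = p_grp,
                    unstandardized = ihs_unstandardized(ihh_a, ihh_d))
  res <- standardize_ihs(res, params$n_bins, params$min_bin_count)

  out <- data.frame(snp_id = sub$snps$snp_id,
                    chromosome = sub$snps$chromosome,
                    position_bp = pos,
                    statistic = "ABS_IHS", group = group,
                    value = res$abs_standardized,
                    maf_global = maf_global,
                    maf_group = pmin(p_grp, 1 - p_grp),
                    derived_freq_group = p_grp,
                    ihh_a = ihh_a, ihh_d = ihh_d,
                    ihs_unstd = res$unstandardized,
                    ihs = res$standardized,
                    freq_bin = res$freq_bin,
                    qc_flag = qc,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_score_track", "data.frame")
  out
}
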