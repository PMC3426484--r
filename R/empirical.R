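#' Assign SNPs to bins of similar minor allele frequency
#'
#' Scored SNPs are sorted by MAF (ties broken by position, then snp_id)
#' and chunked into consecutive bins of `snps_per_bin`; a final partial
#' bin smaller than half the target is merged into its neighbor. The
#' genome-scale default bin size is 10,000 SNPs; scaled-down runs pass a
#' smaller value.
#'
#' @param track a `snp_score_track` for one group x statistic (rows with
#'   missing `value` are left unbinned)
#' @param snps_per_bin target bin size (default 10000)
#' @return a list of class `maf_binning` with `bin_id` (per track row,
#'   `NA` for unscored rows) and `bins` (data frame `bin_id`,
#'   `snp_count`, `maf_min`, `maf_max`).
#' @export
assign_maf_bins <- function(track, snps_per_bin = 10000L) {
  stopifnot(all(c("value", "maf_global") %in% names(track)))
  scored <- which(!is.na(track$value))
  n <- length(scored)
  bin_id <- rep(NA_integer_, nrow(track))
  if (n == 0) stop("no scored SNPs to bin")
  if (n < snps_per_bin)
    warning("fewer scored SNPs (", n, ") than snps_per_bin (", snps_per_bin,
            "); using a single bin")
  ord <- scored[order(track$maf_global[scored], track$position_bp[scored],
                      track$snp_id[scored])]
  b <- (seq_len(n) - 1L) %/% snps_per_bin + 1L
  n_bins <- max(b)
  if (n_bins > 1 && sum(b == n_bins) < snps_per_bin / 2)
    b[b == n_bins] <- n_bins - 1L
  bin_id[ord] <- b
  bins <- do.call(rbind, lapply(sort(unique(b)), function(k) {
    idx <- ord[b == k]
    data.frame(bin_id = k, snp_count = length(idx),
               maf_min = min(track$maf_global[idx]),
               maf_max = max(track$maf_global[idx]))
  }))
  structure(list(bin_id = bin_id, bins = bins), class = "maf_binning")
}

#' Empirical p-values within MAF bins
#'
#' For each scored SNP, `p = (g + 1) / (n_bin + 1)` where `g` is the
#' number of SNPs in the same bin with a strictly greater score and
#' `n_bin` the bin size. The `+1` correction bounds p away from 0 (the
#' literal proportion would give the top SNP p = 0 and break the
#' downstream Fisher log) while preserving the ranking exactly; p is
#' always in `(0, 1)`.
#'
#' @param track a `snp_score_track`
#' @param binning the matching [assign_maf_bins()] result
#' @return `track` with added columns `bin_id` and `emp_p` (missing
#'   scores get missing p).
#' @export
empirical_p <- function(track, binning) {
  stopifnot(inherits(binning, "maf_binning"),
            length(binning$bin_id) == nrow(track))
  emp <- rep(NA_real_, nrow(track))
  for (k in unique(binning$bin_id[!is.na(binning$bin_id)])) {
    idx <- which(binning$bin_id == k & !is.na(track$value))
    s <- track$value[idx]
    n <- length(s)
    greater <- n - rank(s, ties.method = "max")
    emp[idx] <- (greater + 1) / (n + 1)
  }
  track$bin_id <- binning$bin_id
  track$emp_p <- emp
  track
}
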