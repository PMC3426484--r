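#' Pipeline configuration
#'
#' Defaults match the study protocol: MAF filter 0.05 (globally and
#' within each group), gene regions of +/- 100 kb, MAF bins of 10,000
#' SNPs, empirical significance at alpha = 0.05 Bonferroni-corrected over
#' 7 continental groups x 2 statistics. Scaled-down synthetic runs
#' override `flank_bp` and `snps_per_bin`.
#'
#' @param statistics subset of `c("FST", "ABS_IHS")`
#' @param flank_bp gene-region flank (default 100000)
#' @param maf_threshold global MAF filter (default 0.05)
#' @param per_group_maf within-group MAF filter (default 0.05)
#' @param snps_per_bin MAF-bin size for empirical p-values (default 10000)
#' @param alpha empirical significance level (default 0.05)
#' @param n_methods statistics counted in the Bonferroni multiplier
#'   (default: number of `statistics`)
#' @param estimator F_ST estimator (see [fst_snp()])
#' @param ihs an [ihs_params()]
#' @param centrality_convention see [compute_centralities()]
#' @param seed integer seed recorded in the manifest
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(statistics = c("FST", "ABS_IHS"),
                            flank_bp = 100000, maf_threshold = 0.05,
                            per_group_maf = 0.05, snps_per_bin = 10000L,
                            alpha = 0.05, n_methods = NULL,
                            estimator = "weir_cockerham",
                            ihs = ihs_params(),
                            centrality_convention = "centiscape",
                            seed = 1L) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (is.null(n_methods)) n_methods <- length(statistics)
  structure(list(statistics = statistics, flank_bp = flank_bp,
                 maf_threshold = maf_threshold,
                 per_group_maf = per_group_maf,
                 snps_per_bin = as.integer(snps_per_bin), alpha = alpha,
                 n_methods = n_methods, estimator = estimator, ihs = ihs,
                 centrality_convention = centrality_convention,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full selection-scan pipeline
#'
#' Stages, in dependency order: global MAF filter, per-SNP scans (F_ST
#' and/or |iHS|) per continental group, MAF-binned empirical p-values per
#' track, gene-level Fisher combination for the pathway and the
#' background catalogs, empirical significance calls with Bonferroni
#' correction, part-comparison tests (event-count chi-square,
#' Mann-Whitney on gene scores, hypergeometric versus background), and
#' network-centrality association. Progress is logged at stage
#' granularity with SNP/gene drop counts.
#'
#' @param data list with `panel`, `scheme`, `catalog`, `annotation`,
#'   `graph`, `background` (as from [simulate_study()] or assembled from
#'   [read_haplotype_vcf()] + [read_tables()])
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, every stage table plus
#'   the manifest is written with [write_results_tsv()]
#' @param verbose log stage messages (default `TRUE`)
#' @return list of class `pathscan_bundle` with elements `tracks`,
#'   `gene_results`, `background_results`, `part_events`, `part_chi2`,
#'   `part_rank_tests`, `hypergeometric`, `centralities`,
#'   `centrality_tests`, `summary`, `config`.
#' @export
run_full_pipeline <- function(data, config = pipeline_config(),
                              out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[pathscan] ", ...)
  need <- c("panel", "scheme", "catalog", "annotation", "background")
  missing_in <- setdiff(need, names(data))
  if (length(missing_in) > 0)
    stop("pipeline input lacks: ", paste(missing_in, collapse = ", "))

  n0 <- n_snps(data$panel)
  panel <- filter_maf(data$panel, config$maf_threshold, "global")
  say("MAF filter: ", n0 - n_snps(panel), " of ", n0, " SNPs dropped (MAF < ",
      config$maf_threshold, ")")
  scheme <- data$scheme

  tracks <- list()
  if ("FST" %in% config$statistics) {
    say("F_ST scan (", config$estimator, ") over ",
        length(scheme$groups), " groups")
    tracks$fst <- fst_scan(panel, scheme, config$estimator,
                           per_group_maf = config$per_group_maf)
  }
  if ("ABS_IHS" %in% config$statistics) {
    say("iHS scan over ", length(scheme$groups), " groups")
    tracks$ihs <- do.call(rbind, lapply(scheme$groups, function(g) {
      tr <- ihs_scan(panel, scheme, g, config$ihs)
      say("  iHS ", g, ": ", sum(tr$qc_flag != "ok"), " of ", nrow(tr),
          " SNPs failed QC")
      tr[, c("snp_id", "chromosome", "position_bp", "statistic", "group",
             "value", "maf_global", "maf_group", "derived_freq_group")]
    }))
  }
  say("empirical p-values (bins of ", config$snps_per_bin, " SNPs)")
  scored <- do.call(rbind, lapply(tracks, function(tr) {
    do.call(rbind, lapply(split(tr, tr$group), function(one) {
      binning <- suppressWarnings(assign_maf_bins(one, config$snps_per_bin))
      empirical_p(one, binning)
    }))
  }))
  rownames(scored) <- NULL
  class(scored) <- c("snp_score_track", "data.frame")

  say("gene-level Fisher combination (flank ", config$flank_bp, " bp)")
  gene_res <- gene_scan(scored, data$catalog, config$flank_bp)
  say("background scan over ", nrow(data$background), " regions")
  bg_res <- background_scan(data$background, scored, config$flank_bp)
  n_groups <- length(scheme$groups)
  gene_res <- empirical_gene_significance(gene_res, bg_res, config$alpha,
                                          n_groups, config$n_methods)
  bg_res <- empirical_gene_significance(bg_res, bg_res, config$alpha,
                                        n_groups, config$n_methods)
  gene_res <- merge(gene_res,
                    data$annotation[, c("gene_id", "sub_pathway", "part")],
                    by = "gene_id", all.x = TRUE, sort = FALSE)
  class(gene_res) <- c("gene_region_result", "data.frame")

  part_events <- list(); part_chi2 <- list(); part_rank <- list(); hyper <- list()
  for (s in config$statistics) {
    ev <- count_events_by_part(gene_res, data$annotation, s)
    ev$statistic <- s
    part_events[[s]] <- ev
    part_chi2[[s]] <- tryCatch({
      x <- chi2_goodness_of_fit(ev)
      data.frame(statistic = s, chi2 = x$chi2, df = x$df, p = x$p)
    }, error = function(e) {
      say("part chi-square skipped for ", s, ": ", conditionMessage(e))
      NULL
    })
    part_rank[[s]] <- do.call(rbind, lapply(scheme$groups, function(g) {
      mw <- tryCatch(compare_part_scores(gene_res, data$annotation, s, g),
                     error = function(e) NULL)
      if (is.null(mw)) return(NULL)
      data.frame(statistic = s, group = g, n_upstream = mw$n1,
                 n_downstream = mw$n2, rank_sum_upstream = mw$rank_sum_1,
                 rank_sum_downstream = mw$rank_sum_2, U = mw$U, Z = mw$Z,
                 p = mw$p_two_sided, stringsAsFactors = FALSE)
    }))
    bg_events <- tapply(bg_res$significant[bg_res$statistic == s],
                        bg_res$gene_id[bg_res$statistic == s], any)
    hyper[[s]] <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
      h <- hypergeometric_part_test(ev$n_genes[i], ev$n_events[i],
                                    length(bg_events), sum(bg_events))
      data.frame(statistic = s, part = ev$part[i],
                 observed = ev$n_events[i], expected = h$expected,
                 p_under = h$p_under, p_over = h$p_over,
                 stringsAsFactors = FALSE)
    }))
  }

  centralities <- NULL; centrality_tests <- NULL
  if (!is.null(data$graph)) {
    say("network centralities (", config$centrality_convention, " convention)")
    centralities <- compute_centralities(data$graph,
                                         config$centrality_convention)
    centrality_tests <- do.call(rbind, lapply(config$statistics, function(s) {
      sig <- tapply(gene_res$significant[gene_res$statistic == s],
                    gene_res$gene_id[gene_res$statistic == s], any)
      sig_genes <- names(sig)[sig]
      ct <- tryCatch(centrality_association(centralities, sig_genes),
                     error = function(e) {
                       say("centrality association skipped for ", s, ": ",
                           conditionMessage(e))
                       NULL
                     })
      if (is.null(ct)) return(NULL)
      cbind(statistic = s, ct)
    }))
  }

  bundle <- structure(list(
    tracks = scored,
    gene_results = gene_res,
    background_results = bg_res,
    part_events = do.call(rbind, part_events),
    part_chi2 = do.call(rbind, part_chi2),
    part_rank_tests = do.call(rbind, part_rank),
    hypergeometric = do.call(rbind, hyper),
    centralities = centralities,
    centrality_tests = centrality_tests,
    config = config), class = "pathscan_bundle")
  bundle$summary <- report(bundle)

  if (!is.null(out_dir)) {
    tables <- Filter(Negate(is.null),
                     bundle[c("tracks", "gene_results", "background_results",
                              "part_events", "part_chi2", "part_rank_tests",
                              "hypergeometric", "centralities",
                              "centrality_tests")])
    tables <- lapply(tables, as.data.frame)
    files <- write_results_tsv(tables, out_dir,
                               config = unclass(config)[
                                 !vapply(config, is.list, logical(1))],
                               seed = config$seed)
    writeLines(bundle$summary, file.path(out_dir, "summary.txt"))
    say("wrote ", length(files) + 1L, " files to ", out_dir)
  }
  bundle
}

#' Plain-text summary report of a pipeline bundle
#'
#' Lists the significant genes per group and statistic (sub-pathway,
#' gene, continental group, raw and corrected p, the layout of the study
#' summary tables), the part-comparison statistics and the
#' centrality-association table.
#'
#' @param bundle a `pathscan_bundle` from [run_full_pipeline()]
#' @return character vector of report lines.
#' @export
report <- function(bundle) {
  fmt_p <- function(p) formatC(p, format = "g", digits = 3)
  lines <- c("pathscan run summary", "====================", "")
  gr <- bundle$gene_results
  for (s in unique(gr$statistic)) {
    lines <- c(lines, paste0("Significant genes (", s, "):"))
    sig <- gr[gr$statistic == s & gr$significant, ]
    if (nrow(sig) == 0) {
      lines <- c(lines, "  none")
    } else {
      sig <- sig[order(sig$gene_id, sig$group), ]
      header <- sprintf("  %-22s %-10s %-18s %-12s %s", "Sub-pathway", "Gene",
                        "Continental Group", "p-value", "Corrected p-value")
      rows <- sprintf("  %-22s %-10s %-18s %-12s %s",
                      ifelse(is.na(sig$sub_pathway), ".", sig$sub_pathway),
                      sig$gene_id, sig$group, fmt_p(sig$p_fisher),
                      fmt_p(sig$corrected_p))
      lines <- c(lines, header, rows)
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$part_chi2)) {
    lines <- c(lines, "Part comparison (event-count chi-square):")
    lines <- c(lines, sprintf("  %s: chi2 = %.3f, p = %s",
                              bundle$part_chi2$statistic,
                              bundle$part_chi2$chi2,
                              fmt_p(bundle$part_chi2$p)), "")
  }
  if (!is.null(bundle$centrality_tests)) {
    ct <- bundle$centrality_tests
    lines <- c(lines, "Centrality association (Mann-Whitney):",
               sprintf("  %-8s %-12s %8s %8s %8s %7s %s", "Stat",
                       "Centrality", "RankSum1", "RankSum2", "U", "Z", "p"),
               sprintf("  %-8s %-12s %8.1f %8.1f %8.1f %7.2f %s",
                       ct$statistic, ct$centrality, ct$rank_sum_1,
                       ct$rank_sum_2, ct$U, ct$Z, fmt_p(ct$p)), "")
  }
  lines
}

#' @export
print.pathscan_bundle <- function(x, ...) {
  cat(x$summary, sep = "\n")
  invisible(x)
}
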