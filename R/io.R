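#' Read a phased VCF into a haplotype panel
#'
#' Reads a VCF with phased genotypes (`|` separator) and an ancestral-allele
#' INFO tag, keeps biallelic SNPs only, and recodes alleles so that 0 is the
#' ancestral allele. Sites whose ancestral allele matches neither REF nor
#' ALT, and sites lacking the ancestral tag, are dropped (with a message /
#' warning); orientation is mandatory for iHS while F_ST is
#' orientation-invariant, so callers that only need F_ST may pass
#' `require_ancestral = FALSE` to keep unoriented sites (REF treated as 0,
#' flagged in the returned `snps` table via `ancestral_known`).
#'
#' @param path VCF file (4.x, plain text or gzipped)
#' @param ancestral_tag INFO key holding the ancestral base (default "AA")
#' @param samples_table optional data frame (`sample_id`, `population`,
#'   `continental_group`); defaults to every VCF sample in population/group
#'   "unknown"
#' @param require_ancestral drop sites without a usable ancestral call
#'   (default `TRUE`)
#' @return a [haplotype_panel()]; the `snps` table gains a logical column
#'   `ancestral_known`.
#' @export
read_haplotype_vcf <- function(path, ancestral_tag = "AA",
                               samples_table = NULL,
                               require_ancestral = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    message("dropping ", sum(!bi), " non-biallelic site(s)")
  gt <- vcfR::extract.gt(v)
  aa <- vcfR::extract.info(v, element = ancestral_tag)
  fix <- fix[bi, , drop = FALSE]
  gt <- gt[bi, , drop = FALSE]
  aa <- toupper(aa[bi])
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)

  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype for sample ", colnames(gt)[w[2]],
         " at site ", fix$ID[w[1]], " (", fix$CHROM[w[1]], ":",
         fix$POS[w[1]], ")")
  }

  aa_usable <- !is.na(aa) & aa %in% c("A", "C", "G", "T")
  matches <- aa_usable & (aa == ref | aa == alt)
  if (any(aa_usable & !matches))
    message("dropping ", sum(aa_usable & !matches),
            " site(s) whose ancestral allele matches neither REF nor ALT")
  if (any(!aa_usable))
    warning(sum(!aa_usable), " site(s) lack a usable ", ancestral_tag,
            " tag", if (require_ancestral) " and were dropped")
  keep <- if (require_ancestral) matches else (matches | !aa_usable)
  if (!any(keep)) stop("no usable sites in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  aa <- aa[keep]
  ref <- ref[keep]
  alt <- alt[keep]
  flip <- aa == alt                 # ALT is ancestral: recode
  flip[is.na(flip)] <- FALSE        # unoriented site kept for F_ST
  ancestral_known <- !is.na(aa) & (aa == ref | aa == alt)

  n_site <- nrow(gt)
  n_smp <- ncol(gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  to_int <- function(a) {
    x <- suppressWarnings(as.integer(a))
    x[!a %in% c("0", "1")] <- NA_integer_
    x
  }
  m1 <- matrix(to_int(a1), nrow = n_site, ncol = n_smp)
  m2 <- matrix(to_int(a2), nrow = n_site, ncol = n_smp)
  # haplotypes: rows 2i-1, 2i = sample i's two phased chromosomes
  hap <- matrix(NA_integer_, nrow = 2L * n_smp, ncol = n_site)
  hap[seq(1L, 2L * n_smp, by = 2L), ] <- t(m1)
  hap[seq(2L, 2L * n_smp, by = 2L), ] <- t(m2)
  if (any(flip))
    hap[, flip] <- 1L - hap[, flip]

  anc <- ifelse(flip, alt, ref)
  der <- ifelse(flip, ref, alt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids,
                     chromosome = fix$CHROM,
                     position_bp = as.integer(fix$POS),
                     ancestral_allele = anc,
                     derived_allele = der,
                     ancestral_known = ancestral_known,
                     stringsAsFactors = FALSE)
  if (is.null(samples_table)) {
    samples_table <- data.frame(sample_id = colnames(gt),
                                population = "unknown",
                                continental_group = "unknown",
                                stringsAsFactors = FALSE)
  } else {
    samples_table <- samples_table[match(colnames(gt), samples_table$sample_id), ]
    if (anyNA(samples_table$sample_id))
      stop("samples table does not cover all VCF samples")
  }
  haplotype_panel(hap, snps, samples_table)
}

#' Write a haplotype panel as a phased VCF
#'
#' Inverse of [read_haplotype_vcf()] for round-trip checks and for feeding
#' simulated panels to external tools. REF is written as the ancestral
#' allele, so no recoding happens on re-read.
#'
#' @param panel a [haplotype_panel()]
#' @param path output file
#' @param ancestral_tag INFO key for the ancestral base
#' @return `path`, invisibly.
#' @export
write_haplotype_vcf <- function(panel, path, ancestral_tag = "AA") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##INFO=<ID=", ancestral_tag,
                      ",Number=1,Type=String,Description=\"Ancestral allele\">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples$sample_id),
                   collapse = "\t"), con)
  h <- panel$haplotypes
  n <- nrow(panel$samples)
  odd <- seq(1L, 2L * n, by = 2L)
  g1 <- h[odd, , drop = FALSE]
  g2 <- h[odd + 1L, , drop = FALSE]
  chr1 <- ifelse(is.na(g1), ".", g1)
  chr2 <- ifelse(is.na(g2), ".", g2)
  gt <- matrix(paste0(chr1, "|", chr2), nrow = n)
  body <- vapply(seq_len(n_snps(panel)), function(j) {
    paste(c(panel$snps$chromosome[j], panel$snps$position_bp[j],
            panel$snps$snp_id[j], panel$snps$ancestral_allele[j],
            panel$snps$derived_allele[j], ".", "PASS",
            paste0(ancestral_tag, "=", panel$snps$ancestral_allele[j]),
            "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose MAF is greater than or equal to `threshold`
#' (inclusive), computed either over all haplotypes (`scope = "global"`)
#' or over one continental group's haplotypes (`scope = "per_group"`).
#' Order is preserved.
#'
#' @param panel a [haplotype_panel()]
#' @param threshold MAF threshold in (0, 0.5]; default 0.05
#' @param scope `"global"` or `"per_group"`
#' @param scheme a [group_scheme()] (required for `per_group`)
#' @param group group label (required for `per_group`)
#' @return filtered `haplotype_panel`.
#' @export
filter_maf <- function(panel, threshold = 0.05, scope = c("global", "per_group"),
                       scheme = NULL, group = NULL) {
  scope <- match.arg(scope)
  stopifnot(threshold > 0, threshold <= 0.5)
  rows <- NULL
  if (scope == "per_group") {
    if (is.null(scheme) || is.null(group))
      stop("per_group scope needs scheme and group")
    rows <- group_hap_rows(panel, scheme, group)
  }
  maf <- panel_maf(panel, rows)
  keep <- !is.na(maf) & maf >= threshold
  if (!any(keep)) stop("no SNPs survive filter")
  subset_snps(panel, keep)
}

#' Read the gene catalog, pathway annotation, group scheme and graph
#'
#' All inputs are TSV with headers except the gene catalog, which may also
#' be a headerless 4-column BED (`format = "bed"`, half-open 0-based,
#' converted to 1-based inclusive at the boundary).
#'
#' @param gene_catalog_path genes: TSV (`gene_id`, `chromosome`,
#'   `tx_start`, `tx_end`) or BED (`chrom start end name`)
#' @param annotation_path TSV (`gene_id`, `sub_pathway`, `part`)
#' @param groups_path TSV (`sample_id`, `population`, `continental_group`)
#' @param edgelist_path TSV (`from`, `to`)
#' @param gene_format `"tsv"` or `"bed"`
#' @return list with elements `catalog`, `annotation`, `scheme`, `graph`,
#'   `samples`.
#' @export
read_tables <- function(gene_catalog_path, annotation_path, groups_path,
                        edgelist_path, gene_format = c("tsv", "bed")) {
  gene_format <- match.arg(gene_format)
  catalog <- read_gene_catalog(gene_catalog_path, gene_format)
  annotation <- pathway_annotation(
    utils::read.delim(annotation_path, stringsAsFactors = FALSE))
  smp <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  scheme <- group_scheme(smp$sample_id, smp$continental_group)
  el <- utils::read.delim(edgelist_path, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(el$from, el$to)), annotation$gene_id)
  if (length(unknown) > 0)
    stop("edge list names unannotated gene(s): ",
         paste(unknown, collapse = ", "))
  graph <- pathway_graph(el, nodes = annotation$gene_id)
  list(catalog = catalog, annotation = annotation, scheme = scheme,
       graph = graph, samples = smp)
}

#' @rdname read_tables
#' @param path gene catalog file
#' @param format `"tsv"` or `"bed"`
#' @export
read_gene_catalog <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED gene catalog needs >= 4 columns")
    df <- data.frame(gene_id = df[[4]], chromosome = df[[1]],
                     tx_start = df[[2]] + 1L,  # 0-based half-open -> 1-based
                     tx_end = df[[3]],
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  gene_catalog(df)
}

#' Write result tables with a run manifest
#'
#' One TSV per table, deterministic column order, `.` for missing values,
#' plus a `manifest.dcf` recording configuration, seed and package
#' versions. Re-running with identical inputs produces byte-identical
#' files.
#'
#' @param tables named list of data frames
#' @param out_dir output directory (created if absent)
#' @param config optional named list recorded in the manifest
#' @param seed optional integer recorded in the manifest
#' @return character vector of files written, invisibly.
#' @export
write_results_tsv <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  files <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE)
    files <- c(files, path)
  }
  manifest <- c(list(package = "pathscan",
                     pathscan_version = as.character(utils::packageVersion("pathscan")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."),
                     seed = if (is.null(seed)) "." else seed,
                     tables = paste(names(tables), collapse = ", ")),
                lapply(config, function(x) paste(format(x), collapse = " ")))
  mpath <- file.path(out_dir, "manifest.dcf")
  write.dcf(as.data.frame(manifest, stringsAsFactors = FALSE), mpath)
  invisible(c(files, mpath))
}

#' Read back a results TSV written by [write_results_tsv()]
#' @param path file path
#' @return data frame with `.` restored to `NA`.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
}
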