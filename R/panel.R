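#' Construct a phased haplotype panel
#'
#' The central data container of the package: a phased 0/1 haplotype matrix
#' oriented so that 0 is the ancestral and 1 the derived allele, together
#' with SNP metadata and sample labels. Haplotype rows come in consecutive
#' pairs, rows `2i - 1` and `2i` belonging to diploid sample `i`.
#'
#' @param haplotypes integer matrix with one row per haplotype (2 per
#'   sample) and one column per SNP; entries 0 (ancestral), 1 (derived)
#'   or `NA` (missing).
#' @param snps data frame with columns `snp_id`, `chromosome`,
#'   `position_bp` (1-based), `ancestral_allele`, `derived_allele` and
#'   optionally `genetic_pos_cM`. Positions must be strictly increasing
#'   within each chromosome and match the column order of `haplotypes`.
#' @param samples data frame with columns `sample_id`, `population`,
#'   `continental_group`; row `i` owns haplotype rows `2i - 1` and `2i`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, snps, samples) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(is.data.frame(snps), is.data.frame(samples))
  need_snp <- c("snp_id", "chromosome", "position_bp",
                "ancestral_allele", "derived_allele")
  missing_cols <- setdiff(need_snp, names(snps))
  if (length(missing_cols) > 0)
    stop("snps table lacks columns: ", paste(missing_cols, collapse = ", "))
  need_smp <- c("sample_id", "population", "continental_group")
  missing_cols <- setdiff(need_smp, names(samples))
  if (length(missing_cols) > 0)
    stop("samples table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(haplotypes) != 2L * nrow(samples))
    stop("haplotype rows (", nrow(haplotypes), ") must equal 2 x samples (",
         2L * nrow(samples), ")")
  if (ncol(haplotypes) != nrow(snps))
    stop("haplotype columns (", ncol(haplotypes), ") must equal SNP rows (",
         nrow(snps), ")")
  bad <- haplotypes[!is.na(haplotypes)]
  if (!all(bad %in% c(0L, 1L)))
    stop("allele codes must be 0, 1 or NA")
  storage.mode(haplotypes) <- "integer"
  for (chr in unique(snps$chromosome)) {
    pos <- snps$position_bp[snps$chromosome == chr]
    if (any(diff(pos) <= 0))
      stop("positions not strictly increasing on chromosome ", chr)
  }
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in snps table")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in samples table")
  rownames(snps) <- NULL
  rownames(samples) <- NULL
  structure(list(haplotypes = haplotypes, snps = snps, samples = samples),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$samples), "samples (",
      nrow(x$haplotypes), "haplotypes ) x", nrow(x$snps), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$snps$chromosome), collapse = ", "), "\n")
  grp <- table(x$samples$continental_group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of SNPs / samples in a panel
#' @param panel a [haplotype_panel()]
#' @return integer count.
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' @rdname n_snps
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' Subset a panel by SNP index
#'
#' @param panel a [haplotype_panel()]
#' @param idx integer or logical index into the SNP columns
#' @return a new `haplotype_panel` with the selected SNPs, order preserved.
#' @export
subset_snps <- function(panel, idx) {
  haplotype_panel(panel$haplotypes[, idx, drop = FALSE],
                  panel$snps[idx, , drop = FALSE],
                  panel$samples)
}

#' Subset a panel by sample
#'
#' Keeps both haplotypes of every retained sample, preserving phase order.
#'
#' @param panel a [haplotype_panel()]
#' @param sample_idx integer or logical index into the sample rows
#' @return a new `haplotype_panel`.
#' @export
subset_samples <- function(panel, sample_idx) {
  sample_idx <- seq_len(nrow(panel$samples))[sample_idx]
  hap_rows <- as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
  haplotype_panel(panel$haplotypes[hap_rows, , drop = FALSE],
                  panel$snps,
                  panel$samples[sample_idx, , drop = FALSE])
}

#' Derived-allele frequency and minor-allele frequency per SNP
#'
#' Frequencies are computed over non-missing haplotypes, optionally
#' restricted to a subset of haplotype rows.
#'
#' @param panel a [haplotype_panel()]
#' @param hap_rows optional integer vector of haplotype rows to use
#' @return numeric vector, one value per SNP (`NaN` where no calls).
#' @export
derived_freq <- function(panel, hap_rows = NULL) {
  h <- if (is.null(hap_rows)) panel$haplotypes
       else panel$haplotypes[hap_rows, , drop = FALSE]
  colMeans(h, na.rm = TRUE)
}

#' @rdname derived_freq
#' @export
panel_maf <- function(panel, hap_rows = NULL) {
  p <- derived_freq(panel, hap_rows)
  pmin(p, 1 - p)
}

#' Construct a continental-group scheme
#'
#' @param sample_id character vector of sample identifiers
#' @param group character vector (parallel to `sample_id`) of
#'   continental-group labels
#' @param groups optional ordered vector of group labels; defaults to order
#'   of first appearance
#' @return an object of class `group_scheme` with fields `groups` and
#'   `assignment` (named character vector sample_id -> group).
#' @export
group_scheme <- function(sample_id, group, groups = NULL) {
  stopifnot(length(sample_id) == length(group))
  if (anyDuplicated(sample_id))
    stop("every sample must be assigned to exactly one group")
  if (is.null(groups)) groups <- unique(group)
  if (!all(group %in% groups))
    stop("group labels outside declared groups: ",
         paste(setdiff(group, groups), collapse = ", "))
  if (length(groups) < 2)
    stop("a group scheme needs at least 2 groups")
  assignment <- stats::setNames(as.character(group), as.character(sample_id))
  structure(list(groups = as.character(groups), assignment = assignment),
            class = "group_scheme")
}

#' Group scheme implied by a panel's sample table
#' @param panel a [haplotype_panel()]
#' @return a [group_scheme()].
#' @export
panel_scheme <- function(panel) {
  group_scheme(panel$samples$sample_id, panel$samples$continental_group)
}

#' Haplotype rows belonging to one continental group
#'
#' @param panel a [haplotype_panel()]
#' @param scheme a [group_scheme()]
#' @param group group label present in `scheme`
#' @return integer vector of haplotype row indices.
#' @export
group_hap_rows <- function(panel, scheme, group) {
  if (!group %in% scheme$groups) stop("unknown group: ", group)
  grp <- scheme$assignment[panel$samples$sample_id]
  if (anyNA(grp))
    stop("samples missing from group scheme: ",
         paste(panel$samples$sample_id[is.na(grp)], collapse = ", "))
  smp <- which(grp == group)
  if (length(smp) == 0) stop("group ", group, " has zero samples")
  sort(c(2L * smp - 1L, 2L * smp))
}

#' Construct and validate a gene catalog
#'
#' Coordinates are 1-based and inclusive on both ends.
#'
#' @param df data frame with columns `gene_id`, `chromosome`, `tx_start`,
#'   `tx_end`
#' @return a validated `gene_catalog` data frame.
#' @export
gene_catalog <- function(df) {
  need <- c("gene_id", "chromosome", "tx_start", "tx_end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("gene catalog lacks columns: ", paste(missing_cols, collapse = ", "))
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0)
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  bad <- df$gene_id[df$tx_start > df$tx_end]
  if (length(bad) > 0)
    stop("tx_start > tx_end for: ", paste(bad, collapse = ", "))
  df <- df[, need]
  df$tx_start <- as.integer(df$tx_start)
  df$tx_end <- as.integer(df$tx_end)
  rownames(df) <- NULL
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Pathway part labels accepted by the annotation
#' @keywords internal
.pathway_parts <- c("upstream", "downstream", "substrates", "excluded")

#' Construct and validate a pathway annotation
#'
#' Maps each gene to a sub-pathway label and to one of the pathway parts
#' `upstream`, `downstream`, `substrates` or `excluded`. Only upstream and
#' downstream genes enter the part-comparison tests; substrates (needed by
#' both parts) and excluded genes are scored but never compared.
#'
#' @param df data frame with columns `gene_id`, `sub_pathway`, `part`
#' @return a validated `pathway_annotation` data frame.
#' @export
pathway_annotation <- function(df) {
  need <- c("gene_id", "sub_pathway", "part")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0)
    stop("duplicate gene_id in annotation: ",
         paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$part), .pathway_parts)
  if (length(bad) > 0)
    stop("unknown part label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.pathway_parts, collapse = ", "), ")")
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("pathway_annotation", "data.frame")
  df
}

#' Construct a simple undirected pathway graph
#'
#' Nodes are genes; an edge means the two gene products share a metabolite.
#' Duplicate edges (in either orientation) collapse to one; self loops are
#' rejected.
#'
#' @param edges data frame with columns `from`, `to` (gene ids)
#' @param nodes character vector of all node gene ids (isolated nodes
#'   allowed); defaults to the genes appearing in `edges`
#' @return an object of class `pathway_graph` with fields `nodes` and
#'   `edges`.
#' @export
pathway_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  nodes <- as.character(nodes)
  loops <- edges$from == edges$to
  if (any(loops))
    stop("self loops not allowed: ", paste(unique(edges$from[loops]), collapse = ", "))
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown) > 0)
    stop("edges name unknown genes: ", paste(unknown, collapse = ", "))
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# igraph view of a pathway_graph (internal)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}
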