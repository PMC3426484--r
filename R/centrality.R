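#' All-pairs shortest-path distances of a pathway graph
#'
#' Unit-weight BFS distances; `Inf` for disconnected pairs.
#'
#' @param graph a [pathway_graph()]
#' @return symmetric numeric matrix with zero diagonal, dimnames = genes.
#' @export
shortest_path_distances <- function(graph) {
  g <- as_igraph(graph)
  d <- igraph::distances(g)
  d[graph$nodes, graph$nodes, drop = FALSE]
}

#' Node centralities of the pathway graph
#'
#' Computes the five centralities used for pathway association tests:
#' \describe{
#'   \item{degree}{number of incident edges.}
#'   \item{eccentricity_c}{reciprocal of the largest distance to any
#'     other node (so larger = more central); the `"classical"`
#'     convention returns the raw maximum distance instead.}
#'   \item{closeness_c}{reciprocal of the total distance to all other
#'     nodes (classical: the total distance itself).}
#'   \item{betweenness}{sum over unordered node pairs (excluding the
#'     node) of the fraction of shortest paths passing through it; raw,
#'     unnormalized.}
#'   \item{centroid}{`min_w (gamma_v(w) - gamma_w(v))` over other nodes
#'     w, where `gamma_v(w)` counts vertices strictly closer to v than to
#'     w (ties count for neither; the count runs over all vertices,
#'     including v and w).}
#' }
#' On a disconnected graph, centralities are computed per connected
#' component with a warning.
#'
#' @param graph a [pathway_graph()]
#' @param convention `"centiscape"` (reciprocal eccentricity/closeness,
#'   default) or `"classical"`
#' @return data frame of class `centrality_table`: `gene_id`, `degree`,
#'   `eccentricity_c`, `closeness_c`, `betweenness`, `centroid`.
#' @export
compute_centralities <- function(graph, convention = c("centiscape", "classical")) {
  convention <- match.arg(convention)
  if (length(graph$nodes) == 0) stop("empty graph")
  g <- as_igraph(graph)
  d <- shortest_path_distances(graph)
  comp <- igraph::components(g)
  if (comp$no > 1)
    warning("graph is disconnected; centralities computed per component")
  n <- length(graph$nodes)
  member <- comp$membership[graph$nodes]

  degree <- igraph::degree(g)[graph$nodes]
  btw <- igraph::betweenness(g, directed = FALSE)[graph$nodes]

  ecc <- numeric(n); clo <- numeric(n); cen <- numeric(n)
  for (v in seq_len(n)) {
    same <- which(member == member[v])
    dv <- d[v, same]
    others <- dv[same != v]
    if (length(others) == 0) {       # isolated node
      ecc[v] <- NA_real_; clo[v] <- NA_real_; cen[v] <- NA_real_
      next
    }
    ecc[v] <- if (convention == "centiscape") 1 / max(others) else max(others)
    clo[v] <- if (convention == "centiscape") 1 / sum(others) else sum(others)
    # centroid: gamma_v(w) - gamma_w(v) minimized over w != v
    f_vw <- vapply(setdiff(same, v), function(w) {
      closer_v <- sum(d[same, v] < d[same, w])
      closer_w <- sum(d[same, w] < d[same, v])
      closer_v - closer_w
    }, numeric(1))
    cen[v] <- min(f_vw)
  }
  out <- data.frame(gene_id = graph$nodes, degree = as.numeric(degree),
                    eccentricity_c = ecc, closeness_c = clo,
                    betweenness = btw, centroid = cen,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Association between node centralities and gene significance
#'
#' For each of the five centralities, a Mann-Whitney test comparing the
#' genes without a significance call (group 1) against the significant
#' genes (group 2), with a Bonferroni flag over the five tests.
#'
#' @param table a [compute_centralities()] result
#' @param significant_genes character vector of significant gene ids
#' @param genes optional explicit set of genes to test (default: all
#'   genes in `table`); the published tests used all 57 pathway genes
#' @return data frame with one row per centrality: `centrality`, `n1`,
#'   `n2`, `rank_sum_1`, `rank_sum_2`, `U`, `Z`, `p`, `p_bonferroni`,
#'   `significant_after_bonferroni`.
#' @export
centrality_association <- function(table, significant_genes, genes = NULL) {
  if (is.null(genes)) genes <- table$gene_id
  tab <- table[table$gene_id %in% genes, ]
  sig <- tab$gene_id %in% significant_genes
  if (!any(sig) || all(sig))
    stop("both significance groups must be non-empty")
  metrics <- c("eccentricity_c" = "Eccentricity", "closeness_c" = "Closeness",
               "betweenness" = "Betweenness", "centroid" = "Centroid",
               "degree" = "Node Degree")
  out <- lapply(names(metrics), function(m) {
    x <- tab[[m]]
    mw <- mann_whitney(x[!sig], x[sig])
    data.frame(centrality = metrics[[m]], n1 = mw$n1, n2 = mw$n2,
               rank_sum_1 = mw$rank_sum_1, rank_sum_2 = mw$rank_sum_2,
               U = mw$U, Z = mw$Z, p = mw$p_two_sided,
               p_bonferroni = min(1, mw$p_two_sided * length(metrics)),
               significant_after_bonferroni =
                 mw$p_two_sided * length(metrics) <= 0.05,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
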