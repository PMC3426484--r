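#' Count significance events per pathway part
#'
#' A gene counts as one event if it is significant in at least one
#' continental group for the given statistic. Only genes annotated
#' `upstream` or `downstream` are counted; substrates and excluded genes
#' never enter the part comparison.
#'
#' @param results a `gene_region_result` with a `significant` column
#' @param annotation a [pathway_annotation()]
#' @param statistic `"FST"` or `"ABS_IHS"`
#' @return data frame with one row per part: `part`, `n_genes`,
#'   `n_events`.
#' @export
count_events_by_part <- function(results, annotation, statistic) {
  stopifnot("significant" %in% names(results))
  res <- results[results$statistic == statistic, ]
  events <- tapply(res$significant, res$gene_id, any)
  out <- lapply(c("upstream", "downstream"), function(p) {
    genes <- annotation$gene_id[annotation$part == p]
    data.frame(part = p, n_genes = length(genes),
               n_events = sum(events[genes], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Goodness-of-fit chi-square on part event counts
#'
#' Expected events per part are proportional to the part's gene count:
#' `E_part = n_genes_part * total_events / total_genes`;
#' `chi2 = sum (O - E)^2 / E` with 1 degree of freedom for two parts.
#'
#' @param counts data frame as from [count_events_by_part()]
#' @return list with `chi2`, `df`, `p`.
#' @export
chi2_goodness_of_fit <- function(counts) {
  total_events <- sum(counts$n_events)
  total_genes <- sum(counts$n_genes)
  if (total_events < 1) stop("no events to test")
  expected <- counts$n_genes * total_events / total_genes
  if (any(expected == 0)) stop("zero expected count in a part")
  chi2 <- sum((counts$n_events - expected)^2 / expected)
  df <- nrow(counts) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Mann-Whitney U test with rank sums and signed Z
#'
#' Midranks are used for ties. `U_i = R_i - n_i (n_i + 1) / 2`,
#' `U = min(U1, U2)`, and the normal deviate is computed from group 1's
#' U: `Z = (U1 - n1 n2 / 2) / sigma` with the tie-corrected
#' `sigma = sqrt(n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1))))`.
#' The two-sided p comes from the normal approximation.
#'
#' @param values_1,values_2 numeric vectors for group 1 and group 2
#' @param tie_correction apply the tie correction to sigma (default
#'   `TRUE`)
#' @return list of class `mann_whitney_result` with `n1`, `n2`,
#'   `rank_sum_1`, `rank_sum_2`, `U1`, `U2`, `U`, `Z`, `p_two_sided`,
#'   `tie_corrected`.
#' @export
mann_whitney <- function(values_1, values_2, tie_correction = TRUE) {
  n1 <- length(values_1); n2 <- length(values_2)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one value")
  v <- c(values_1, values_2)
  r <- rank(v)
  R1 <- sum(r[seq_len(n1)])
  R2 <- sum(r) - R1
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  N <- n1 + n2
  tie_term <- 0
  if (tie_correction) {
    t <- table(v)
    tie_term <- sum(t^3 - t) / (N * (N - 1))
  }
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) stop("degenerate ranking: all values tied")
  Z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
  structure(list(n1 = n1, n2 = n2, rank_sum_1 = R1, rank_sum_2 = R2,
                 U1 = U1, U2 = U2, U = min(U1, U2), Z = Z,
                 p_two_sided = 2 * stats::pnorm(-abs(Z)),
                 tie_corrected = tie_correction),
            class = "mann_whitney_result")
}

#' Reconstruct U from published rank sums
#'
#' `U = min(R1 - n1(n1+1)/2, R2 - n2(n2+1)/2)`; useful for checking
#' printed Mann-Whitney tables, whose rank sums must also satisfy
#' `R1 + R2 = N(N+1)/2`.
#'
#' @param rank_sum_1,rank_sum_2 rank sums of the two groups
#' @param n1,n2 group sizes
#' @return the U statistic.
#' @export
u_from_rank_sums <- function(rank_sum_1, rank_sum_2, n1, n2) {
  pmin(rank_sum_1 - n1 * (n1 + 1) / 2, rank_sum_2 - n2 * (n2 + 1) / 2)
}

#' Compare gene-level scores between the pathway parts
#'
#' Mann-Whitney test of the upstream (group 1) versus downstream
#' (group 2) genes' Fisher Z scores for one continental group and
#' statistic.
#'
#' @param results a `gene_region_result`
#' @param annotation a [pathway_annotation()]
#' @param statistic `"FST"` or `"ABS_IHS"`
#' @param group continental group label
#' @return a [mann_whitney()] result.
#' @export
compare_part_scores <- function(results, annotation, statistic, group) {
  res <- results[results$statistic == statistic & results$group == group, ]
  z <- stats::setNames(res$z_fisher, res$gene_id)
  up <- z[annotation$gene_id[annotation$part == "upstream"]]
  down <- z[annotation$gene_id[annotation$part == "downstream"]]
  up <- up[!is.na(up)]; down <- down[!is.na(down)]
  if (length(up) == 0 || length(down) == 0)
    stop("a pathway part has no scored genes for ", statistic, "/", group)
  mann_whitney(up, down)
}

#' Hypergeometric enrichment test of a pathway part
#'
#' The population is the union of the background genes and the part's
#' genes; `K` significant genes exist in total, and the part draws
#' `n_genes` of the population. `p_under = P[X <= observed]` and
#' `p_over = P[X >= observed]` for the hypergeometric X; the two share
#' the observed point mass, so `p_under + p_over >= 1`.
#'
#' @param part_n genes in the part
#' @param part_events significant genes in the part
#' @param background_n background genes
#' @param background_events significant background genes
#' @return list with `p_under`, `p_over`, `expected` (the expected event
#'   count for the part).
#' @export
hypergeometric_part_test <- function(part_n, part_events,
                                     background_n, background_events) {
  if (background_events > background_n)
    stop("background events exceed background size")
  if (part_events > part_n) stop("part events exceed part size")
  N <- background_n + part_n
  K <- background_events + part_events
  if (part_n > N) stop("part larger than population")
  p_under <- stats::phyper(part_events, K, N - K, part_n)
  p_over <- stats::phyper(part_events - 1, K, N - K, part_n,
                          lower.tail = FALSE)
  list(p_under = p_under, p_over = p_over, expected = part_n * K / N)
}
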