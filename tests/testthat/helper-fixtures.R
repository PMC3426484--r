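# Shared fixture builders and independent oracles.

# minimal panel from a haplotype matrix (one chromosome, unit spacing
# unless positions given)
make_panel <- function(hap, positions = NULL, groups = NULL) {
  hap <- as.matrix(hap)
  m <- ncol(hap)
  n <- nrow(hap) / 2
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  if (is.null(groups)) groups <- rep("G1", n)
  haplotype_panel(
    hap,
    data.frame(snp_id = sprintf("s%03d", seq_len(m)), chromosome = "chr1",
               position_bp = as.integer(positions),
               ancestral_allele = "A", derived_allele = "G",
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("I%03d", seq_len(n)),
               population = groups, continental_group = groups,
               stringsAsFactors = FALSE))
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("NA1", "NA2")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# independent Weir-Cockerham (1984) haploid transcription via the
# a / b variance components (the implementation uses the MSP/MSG form)
wc_oracle <- function(n1, d1, n2, d2) {
  p1 <- d1 / n1; p2 <- d2 / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  a <- nbar / nc * (s2 - b / nbar)
  a / (a + b)
}

# brute-force EHH: probability that two random distinct carriers are
# identical over every site from the core to x (pairwise O(n^2 m))
ehh_pairwise_oracle <- function(hap, carriers, core_idx, to_idx) {
  span <- if (to_idx >= core_idx) core_idx:to_idx else core_idx:to_idx
  n <- length(carriers)
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all(hap[carriers[i], span] == hap[carriers[j], span]))
        same <- same + 1L
    }
  }
  same / (n * (n - 1) / 2)
}

# closed-form upper chi-square tail for even df = 2k:
# P[X > z] = exp(-z/2) * sum_{j=0}^{k-1} (z/2)^j / j!
chisq_tail_oracle <- function(z, k) {
  exp(-z / 2) * sum((z / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# exact hypergeometric tail by direct summation of the point masses
hyper_under_oracle <- function(obs, K, N, n_draw) {
  sum(vapply(0:obs, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n_draw - x) - lchoose(N, n_draw))
  }, numeric(1)))
}

# --- brute-force graph centrality oracles (independent of igraph) ---

# BFS distances from an adjacency matrix
bfs_dist_oracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier) > 0) {
      lev <- lev + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- lev
      frontier <- nxt
    }
  }
  d
}

# exhaustive shortest-path enumeration for betweenness: counts all
# shortest s-t paths via recursive extension over the BFS DAG
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  d <- bfs_dist_oracle(adj)
  count_paths <- function(s, t) {
    # returns list(total, through = vector of interior-vertex counts)
    through <- numeric(n)
    total <- 0
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        total <<- total + 1
        interior <- setdiff(path, c(s, t))
        through[interior] <<- through[interior] + 1
        return(invisible())
      }
      for (w in which(adj[v, ] == 1)) {
        if (d[s, w] == d[s, v] + 1 && d[w, t] == d[v, t] - 1) walk(c(path, w))
      }
    }
    walk(s)
    list(total = total, through = through)
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      cp <- count_paths(s, t)
      btw <- btw + cp$through / cp$total
    }
  }
  btw
}

centroid_oracle <- function(adj) {
  n <- nrow(adj)
  d <- bfs_dist_oracle(adj)
  vapply(seq_len(n), function(v) {
    min(vapply(setdiff(seq_len(n), v), function(w) {
      sum(d[, v] < d[, w]) - sum(d[, w] < d[, v])
    }, numeric(1)))
  }, numeric(1))
}

adj_to_graph <- function(adj) {
  n <- nrow(adj)
  ids <- sprintf("n%d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  pathway_graph(data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                           stringsAsFactors = FALSE), nodes = ids)
}

is_connected_adj <- function(adj) all(is.finite(bfs_dist_oracle(adj)))

# small default study fixture for pipeline-level tests
small_study <- function(seed = 11, sweep = NULL, wright_F = 0.08) {
  cfg <- sim_config(seed = seed, n_groups = 3, samples_per_group = 12,
                    n_snps = 700, chromosome_length_bp = 4e6,
                    wright_F = wright_F, sweep = sweep,
                    gene_count = 12, gene_length_bp = 4000,
                    flank_bp = 8000, background_region_count = 40)
  simulate_study(cfg)
}

small_pipeline_config <- function(...) {
  pipeline_config(flank_bp = 8000, snps_per_bin = 300,
                  ihs = ihs_params(min_bin_count = 5), ...)
}
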