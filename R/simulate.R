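#' Simulation configuration for HGDP-like synthetic panels
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' structure of the real study panel at desk scale: seven labelled
#' continental groups, phased biallelic SNPs with known ancestral allele,
#' an array-like (roughly uniform) MAF spectrum, Balding-Nichols
#' between-group differentiation, optional founder-mosaic selective sweep,
#' and a pathway of 57 genes (25 upstream, 21 downstream, 10 substrates,
#' 1 excluded) plus a disjoint background catalog.
#'
#' @param seed integer master seed; every stage derives its own stream from
#'   it so toggling the sweep leaves the neutral background untouched
#' @param n_groups number of continental groups (default 7)
#' @param samples_per_group diploid samples per group (default 30)
#' @param n_snps SNP sites simulated before the MAF floor is applied
#' @param chromosome_length_bp chromosome length (default 24 Mb, giving
#'   roughly the study's 1 SNP / 5 kb density at the default `n_snps`)
#' @param wright_F Wright's F of the Balding-Nichols model, in `[0, 1)`
#' @param copy_switch_rate per-bp template-switch rate of the Markov
#'   copying pass that induces linkage disequilibrium
#' @param maf_floor global MAF floor enforced by construction (default
#'   0.05, the study's filter)
#' @param sweep `NULL` or a list from [sweep_params()]
#' @param gene_count number of pathway genes (default 57)
#' @param gene_length_bp gene body length for tiled fixture genes
#' @param flank_bp flank used when tiling non-overlapping regions (scaled
#'   down from the analysis default of 100 kb so that pathway + background
#'   regions fit on one chromosome)
#' @param background_region_count background regions (default 500; the
#'   real-data background used 6,450)
#' @param part_counts named integer vector giving how many genes get each
#'   part label; must sum to `gene_count`
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_groups = 7L,
                       samples_per_group = 30L,
                       n_snps = 5000L,
                       chromosome_length_bp = 24e6,
                       wright_F = 0.1,
                       copy_switch_rate = 1e-5,
                       maf_floor = 0.05,
                       sweep = NULL,
                       gene_count = 57L,
                       gene_length_bp = 4000L,
                       flank_bp = 10000L,
                       background_region_count = 500L,
                       part_counts = NULL) {
  if (is.null(part_counts)) {
    if (gene_count == 57L) {
      part_counts <- c(upstream = 25L, downstream = 21L,
                       substrates = 10L, excluded = 1L)
    } else {
      prop <- c(upstream = 25, downstream = 21, substrates = 10, excluded = 1) / 57
      cts <- diff(c(0, round(cumsum(prop * gene_count))))
      names(cts) <- names(prop)
      part_counts <- cts
    }
  }
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              n_snps = as.integer(n_snps),
              chromosome_length_bp = chromosome_length_bp,
              wright_F = wright_F, copy_switch_rate = copy_switch_rate,
              maf_floor = maf_floor, sweep = sweep,
              gene_count = as.integer(gene_count),
              gene_length_bp = as.integer(gene_length_bp),
              flank_bp = as.integer(flank_bp),
              background_region_count = as.integer(background_region_count),
              part_counts = part_counts)
  stopifnot(cfg$n_groups >= 2, cfg$samples_per_group >= 2, cfg$n_snps >= 2,
            cfg$chromosome_length_bp > cfg$n_snps,
            cfg$wright_F >= 0, cfg$wright_F < 1,
            cfg$maf_floor > 0, cfg$maf_floor <= 0.5,
            sum(part_counts) == cfg$gene_count)
  class(cfg) <- "sim_config"
  cfg
}

#' Sweep parameters for the founder-mosaic sweep
#'
#' The sweep is constructed, not forward-simulated: a target fraction of
#' haplotypes receives the derived core allele and is rebuilt as a mosaic
#' of a single founder haplotype with one-way recombination escapes, so
#' ground truth (carrier set, founder, decay rate) is exact.
#'
#' @param core_position bp position of the swept core (default `NULL`:
#'   chromosome midpoint)
#' @param derived_frequency target derived frequency at the core, in (0,1)
#' @param founder_fraction fraction of carriers rebuilt as founder mosaics
#' @param recomb_switch_rate per-bp escape rate off the founder haplotype
#' @param span_bp half-width of the rebuilt region around the core
#'   (default 100 kb; `Inf` rebuilds the whole chromosome)
#' @return a list of class `sweep_params`.
#' @export
sweep_params <- function(core_position = NULL, derived_frequency = 0.6,
                         founder_fraction = 1.0, recomb_switch_rate = 5e-8,
                         span_bp = 1e5) {
  stopifnot(derived_frequency > 0, derived_frequency < 1,
            founder_fraction >= 0, founder_fraction <= 1,
            recomb_switch_rate >= 0, span_bp > 0)
  structure(list(core_position = core_position,
                 derived_frequency = derived_frequency,
                 founder_fraction = founder_fraction,
                 recomb_switch_rate = recomb_switch_rate,
                 span_bp = span_bp),
            class = "sweep_params")
}

# deterministic per-stage substream of the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Balding-Nichols per-group derived-allele frequencies
#'
#' Each group's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `p(1-p)F`. `F = 0` returns `p_anc` exactly for every group.
#'
#' @param p_anc ancestral (shared) derived-allele frequency in (0,1);
#'   vectorized
#' @param wright_F Wright's F in `[0, 1)`
#' @param n_groups number of groups
#' @return matrix `n_groups x length(p_anc)` of frequencies.
#' @export
simulate_frequencies <- function(p_anc, wright_F, n_groups) {
  stopifnot(all(p_anc > 0), all(p_anc < 1))
  m <- length(p_anc)
  if (wright_F == 0)
    return(matrix(rep(p_anc, each = n_groups), nrow = n_groups))
  scale <- (1 - wright_F) / wright_F
  a <- rep(p_anc * scale, each = n_groups)
  b <- rep((1 - p_anc) * scale, each = n_groups)
  matrix(stats::rbeta(n_groups * m, a, b), nrow = n_groups)
}

#' Simulate a structured haplotype panel
#'
#' SNP positions are uniform-sorted along one chromosome; neutral
#' haplotypes are drawn site-wise from Balding-Nichols group frequencies;
#' linkage disequilibrium is then induced by a Markov copying pass in which
#' each haplotype is rebuilt as a mosaic of its group's base haplotypes,
#' switching template at `copy_switch_rate` per bp. If the configuration
#' carries sweep parameters the sweep is implanted, and finally the global
#' MAF floor is enforced by construction (violating columns are dropped),
#' so the returned panel may have fewer than `n_snps` columns.
#'
#' @param config a [sim_config()]
#' @return a [haplotype_panel()]; when a sweep was implanted the panel has
#'   an attribute `sweep` with the ground truth (`core_snp_id`,
#'   `carrier_rows`, `founder_row`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_hap_grp <- 2L * config$samples_per_group
  n_grp <- config$n_groups
  m <- config$n_snps

  set.seed(stage_seed(config$seed, 1L))
  positions <- sort(sample.int(config$chromosome_length_bp, m))
  p_anc <- stats::runif(m, config$maf_floor, 1 - config$maf_floor)
  freqs <- simulate_frequencies(p_anc, config$wright_F, n_grp)

  base <- matrix(0L, nrow = n_grp * n_hap_grp, ncol = m)
  for (g in seq_len(n_grp)) {
    rows <- (g - 1L) * n_hap_grp + seq_len(n_hap_grp)
    base[rows, ] <- (matrix(stats::runif(n_hap_grp * m), n_hap_grp, m) <
                       matrix(freqs[g, ], n_hap_grp, m, byrow = TRUE)) + 0L
  }

  # Markov copying pass: mosaic of same-group base haplotypes
  set.seed(stage_seed(config$seed, 2L))
  gaps <- diff(positions)
  p_switch <- 1 - exp(-config$copy_switch_rate * gaps)
  hap <- base
  for (g in seq_len(n_grp)) {
    rows <- (g - 1L) * n_hap_grp + seq_len(n_hap_grp)
    for (h in rows) {
      switches <- c(TRUE, stats::runif(m - 1L) < p_switch)
      seg <- cumsum(switches)
      templates <- sample(setdiff(rows, h), max(seg), replace = TRUE)
      hap[h, ] <- base[cbind(templates[seg], seq_len(m))]
    }
  }

  labels <- .group_labels(n_grp)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_grp * config$samples_per_group)),
    population = rep(labels, each = config$samples_per_group),
    continental_group = rep(labels, each = config$samples_per_group),
    stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(m)),
                     chromosome = "chr1",
                     position_bp = positions,
                     ancestral_allele = "A",
                     derived_allele = "G",
                     stringsAsFactors = FALSE)
  panel <- haplotype_panel(hap, snps, samples)

  sweep_truth <- NULL
  if (!is.null(config$sweep)) {
    panel <- implant_sweep(panel, config$sweep,
                           seed = stage_seed(config$seed, 3L))
    sweep_truth <- attr(panel, "sweep")
  }
  maf <- panel_maf(panel)
  keep <- maf >= config$maf_floor
  if (!any(keep)) stop("no SNPs survive the MAF floor")
  out <- subset_snps(panel, keep)
  if (!is.null(sweep_truth)) {
    if (!sweep_truth$core_snp_id %in% out$snps$snp_id)
      warning("sweep core dropped by the MAF floor")
    attr(out, "sweep") <- sweep_truth
  }
  out
}

.group_labels <- function(n) {
  hgdp <- c("SSAFR", "MENA", "EUR", "CSASIA", "EASIA", "OCE", "AME")
  if (n <= length(hgdp)) hgdp[seq_len(n)] else sprintf("GRP%02d", seq_len(n))
}

#' Implant a founder-mosaic selective sweep
#'
#' A target fraction of haplotypes is made to carry the derived allele at
#' the core SNP; `founder_fraction` of those carriers are rebuilt, within
#' `span_bp` of the core, as copies of one founder haplotype with one-way
#' recombination escapes at `recomb_switch_rate` per bp (once escaped, a
#' carrier returns to its own background). EHH around the core therefore
#' decays more slowly for derived carriers; non-carriers are untouched.
#'
#' @param panel a [haplotype_panel()]
#' @param params a [sweep_params()]
#' @param seed integer seed for the sweep stream
#' @return the panel with the sweep implanted and a `sweep` attribute
#'   holding the ground truth.
#' @export
implant_sweep <- function(panel, params, seed = 1L) {
  stopifnot(inherits(params, "sweep_params"))
  pos <- panel$snps$position_bp
  core_pos <- params$core_position
  if (is.null(core_pos)) core_pos <- stats::median(range(pos))
  if (core_pos < min(pos) || core_pos > max(pos))
    stop("sweep core position outside the panel's SNP range")
  core <- which.min(abs(pos - core_pos))
  n_hap <- nrow(panel$haplotypes)
  target <- round(params$derived_frequency * n_hap)
  if (target < 2 || target > n_hap - 1)
    stop("requested derived_frequency unreachable given panel size")

  set.seed(seed)
  carriers <- sort(sample.int(n_hap, target))
  founder <- carriers[sample.int(length(carriers), 1L)]
  n_rebuild <- round(params$founder_fraction * length(carriers))
  rebuilt <- sort(sample(carriers, n_rebuild))

  hap <- panel$haplotypes
  in_span <- abs(pos - pos[core]) <= params$span_bp
  founder_row <- hap[founder, ]
  rate <- params$recomb_switch_rate
  for (h in setdiff(rebuilt, founder)) {
    esc_right <- if (rate > 0) stats::rexp(1, rate) else Inf
    esc_left <- if (rate > 0) stats::rexp(1, rate) else Inf
    copy <- in_span &
      ((pos >= pos[core] & pos - pos[core] <= esc_right) |
       (pos < pos[core] & pos[core] - pos <= esc_left))
    hap[h, copy] <- founder_row[copy]
  }
  hap[, core] <- 0L
  hap[carriers, core] <- 1L

  out <- haplotype_panel(hap, panel$snps, panel$samples)
  attr(out, "sweep") <- list(core_snp_id = panel$snps$snp_id[core],
                             core_position = pos[core],
                             carrier_rows = carriers,
                             founder_row = founder)
  out
}

#' Generate the pathway fixture: genes, annotation, graph, background
#'
#' Tiles `gene_count` pathway genes and `background_region_count`
#' background genes on the simulated chromosome so that the regions
#' (gene body plus `flank_bp` on each side) are pairwise non-overlapping.
#' Pathway genes are annotated with part labels in the configured
#' proportions and sub-pathway labels within each part, and connected by a
#' simple path-plus-branches graph.
#'
#' @param config a [sim_config()]
#' @return list with `catalog`, `annotation`, `graph` and `background`
#'   (a background [gene_catalog()]).
#' @export
make_pathway_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$gene_count < 4) stop("gene_count must be >= 4")
  set.seed(stage_seed(config$seed, 4L))
  n_path <- config$gene_count
  n_bg <- config$background_region_count
  n_tot <- n_path + n_bg
  width <- config$gene_length_bp + 2 * config$flank_bp
  slack <- config$chromosome_length_bp - n_tot * width
  if (slack <= n_tot)
    stop("chromosome too short to tile ", n_tot,
         " non-overlapping regions of ", width, " bp")
  offsets <- sort(stats::runif(n_tot, 0, 1)) * slack
  region_start <- floor(offsets + (seq_len(n_tot) - 1L) * width) + 1L
  tx_start <- as.integer(region_start + config$flank_bp)
  tx_end <- as.integer(tx_start + config$gene_length_bp - 1L)

  which_path <- sort(sample.int(n_tot, n_path))
  path_ids <- sprintf("GENE%03d", seq_len(n_path))
  bg_ids <- sprintf("BG%04d", seq_len(n_bg))
  catalog <- gene_catalog(data.frame(
    gene_id = path_ids, chromosome = "chr1",
    tx_start = tx_start[which_path], tx_end = tx_end[which_path],
    stringsAsFactors = FALSE))
  background <- gene_catalog(data.frame(
    gene_id = bg_ids, chromosome = "chr1",
    tx_start = tx_start[-which_path], tx_end = tx_end[-which_path],
    stringsAsFactors = FALSE))

  part <- rep(names(config$part_counts), config$part_counts)
  part <- sample(part)  # shuffle assignment along the chromosome
  sub <- character(n_path)
  sub_pool <- list(
    upstream = c("precursor_biosynthesis", "ost_complex", "cnx_crt"),
    downstream = c("branching_early_golgi", "branching_late_golgi"),
    substrates = "substrates",
    excluded = "unplaced")
  for (p in unique(part)) {
    idx <- which(part == p)
    pool <- sub_pool[[p]]
    sub[idx] <- pool[1L + (seq_along(idx) - 1L) %% length(pool)]
  }
  annotation <- pathway_annotation(data.frame(
    gene_id = path_ids, sub_pathway = sub, part = part,
    stringsAsFactors = FALSE))

  # connected path backbone plus ~15% random branch edges
  ord <- sample(path_ids)
  edges <- data.frame(from = ord[-n_path], to = ord[-1],
                      stringsAsFactors = FALSE)
  n_extra <- max(1L, round(0.15 * n_path))
  for (k in seq_len(n_extra)) {
    pair <- sample(path_ids, 2L)
    edges <- rbind(edges, data.frame(from = pair[1], to = pair[2]))
  }
  graph <- pathway_graph(edges, nodes = path_ids)

  list(catalog = catalog, annotation = annotation, graph = graph,
       background = background)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper producing everything the pipeline needs: the panel,
#' the group scheme, and the pathway fixture.
#'
#' @param config a [sim_config()]
#' @return list with `panel`, `scheme`, `catalog`, `annotation`, `graph`,
#'   `background`, `config`.
#' @export
simulate_study <- function(config) {
  panel <- simulate_panel(config)
  fixture <- make_pathway_fixture(config)
  c(list(panel = panel, scheme = panel_scheme(panel), config = config),
    fixture)
}
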