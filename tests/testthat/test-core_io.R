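test_that("phased VCF is read into an ancestral-oriented haplotype matrix", {
  lines <- c(vcf_header(), paste(collapse = "\t", c(
    "chr1", "100", "rs1", "A", "G", ".", "PASS", "AA=A", "GT", "0|1", "1|1")),
    paste(collapse = "\t", c(
    "chr1", "200", "rs2", "C", "T", ".", "PASS", "AA=T", "GT", "0|1", "0|0")),
    paste(collapse = "\t", c(
    "chr1", "300", "rs3", "G", "A", ".", "PASS", "AA=G", "GT", "1|0", "0|1")))
  p <- read_haplotype_vcf(write_vcf_fixture(lines))
  expect_s3_class(p, "haplotype_panel")
  expect_identical(dim(p$haplotypes), c(4L, 3L))
  # rs1: AA = REF, codes as written
  expect_identical(p$haplotypes[, 1], c(0L, 1L, 1L, 1L))
  # rs2: AA = ALT, codes flipped relative to REF/ALT coding
  expect_identical(p$haplotypes[, 2], c(1L, 0L, 1L, 1L))
  expect_identical(p$snps$ancestral_allele[2], "T")
  expect_identical(p$snps$derived_allele[2], "C")
  expect_identical(p$haplotypes[, 3], c(1L, 0L, 0L, 1L))
})

test_that("sites with unusable ancestral allele are dropped; unphased errors", {
  lines <- c(vcf_header(), paste(collapse = "\t", c(
    "chr1", "100", "rs1", "A", "G", ".", "PASS", "AA=A", "GT", "0|1", "1|1")),
    paste(collapse = "\t", c(
    "chr1", "200", "rs2", "C", "T", ".", "PASS", "AA=N", "GT", "0|1", "0|0")))
  expect_warning(p <- read_haplotype_vcf(write_vcf_fixture(lines)),
                 "lack a usable")
  expect_equal(n_snps(p), 1L)

  # ancestral allele matching neither REF nor ALT is dropped too
  lines2 <- c(vcf_header(), paste(collapse = "\t", c(
    "chr1", "100", "rs1", "A", "G", ".", "PASS", "AA=A", "GT", "0|1", "1|1")),
    paste(collapse = "\t", c(
    "chr1", "200", "rs2", "C", "T", ".", "PASS", "AA=G", "GT", "0|1", "0|0")))
  expect_message(p2 <- read_haplotype_vcf(write_vcf_fixture(lines2)),
                 "neither REF nor ALT")
  expect_equal(n_snps(p2), 1L)

  bad <- c(vcf_header(), paste(collapse = "\t", c(
    "chr1", "100", "rs1", "A", "G", ".", "PASS", "AA=A", "GT", "0/1", "1|1")))
  expect_error(read_haplotype_vcf(write_vcf_fixture(bad)), "unphased.*NA1")
})

test_that("VCF reader agrees cell-for-cell with a hand-parsed fixture", {
  # 20-line fixture: 16 sites x 3 samples, mixed orientation, one missing
  set.seed(5)
  n_site <- 16
  ref <- sample(c("A", "C"), n_site, replace = TRUE)
  alt <- ifelse(ref == "A", "G", "T")
  aa_is_alt <- rep(c(FALSE, TRUE), length.out = n_site)
  gt_codes <- matrix(sample(0:1, n_site * 6, replace = TRUE), n_site)
  gt_codes[3, 1] <- NA
  gt_str <- sapply(seq_len(n_site), function(i) {
    g <- gt_codes[i, ]
    g <- ifelse(is.na(g), ".", g)
    paste0(g[c(1, 3, 5)], "|", g[c(2, 4, 6)])
  })
  body <- sapply(seq_len(n_site), function(i) paste(collapse = "\t", c(
    "chr2", i * 50, sprintf("v%02d", i), ref[i], alt[i], ".", "PASS",
    paste0("AA=", if (aa_is_alt[i]) alt[i] else ref[i]), "GT", gt_str[, i])))
  p <- read_haplotype_vcf(write_vcf_fixture(c(vcf_header(c("A", "B", "C")),
                                              body)))
  # hand-parsed expectation: flip where AA = ALT
  expected <- t(gt_codes)
  expected[, aa_is_alt] <- 1L - expected[, aa_is_alt]
  expect_identical(p$haplotypes, matrix(as.integer(expected), 6, n_site,
                                        dimnames = NULL))
})

test_that("panel round-trips through VCF write/read", {
  cfg <- sim_config(seed = 3, n_groups = 2, samples_per_group = 5,
                    n_snps = 40, chromosome_length_bp = 2e5,
                    gene_count = 4, background_region_count = 2,
                    flank_bp = 1000, gene_length_bp = 500)
  panel <- simulate_panel(cfg)
  path <- tempfile(fileext = ".vcf")
  write_haplotype_vcf(panel, path)
  back <- read_haplotype_vcf(path, samples_table = panel$samples)
  expect_identical(unname(back$haplotypes), unname(panel$haplotypes))
  expect_equal(back$snps$position_bp, panel$snps$position_bp)
  expect_equal(back$samples$continental_group, panel$samples$continental_group)
})

test_that("MAF filter is inclusive at the threshold and scope-aware", {
  hap <- matrix(0L, nrow = 100, ncol = 3)
  hap[1:3, 1] <- 1L     # MAF 0.03: removed at 0.05
  hap[1:95, 2] <- 1L    # derived 95/100, MAF 0.05: retained (inclusive)
  hap[1:50, 3] <- 1L    # MAF 0.5
  p <- make_panel(hap)
  f <- filter_maf(p, 0.05)
  expect_identical(f$snps$snp_id, c("s002", "s003"))

  # per-group scope: SNP rare globally (MAF 0.04) but at 0.4 inside group A
  snp1 <- c(rep(1L, 4), rep(0L, 96))
  snp2 <- rep(c(0L, 1L), 50)
  p2 <- make_panel(cbind(snp1, snp2), groups = rep(c("A", "B"), c(5, 45)))
  sch <- group_scheme(p2$samples$sample_id, rep(c("A", "B"), c(5, 45)))
  expect_equal(n_snps(filter_maf(p2, 0.05)), 1L)  # global filter drops snp1
  fA <- filter_maf(p2, 0.05, scope = "per_group", scheme = sch, group = "A")
  expect_equal(n_snps(fA), 2L)                    # kept: 0.4 >= 0.05 within A
  fB <- filter_maf(p2, 0.05, scope = "per_group", scheme = sch, group = "B")
  expect_equal(n_snps(fB), 1L)                    # absent from B: dropped
  expect_error(filter_maf(subset_snps(p, 1), 0.05), "no SNPs survive")
})

test_that("table readers validate and convert coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tGENEA", "chr1\t5000\t6000\tGENEB"), bed)
  cat_bed <- read_gene_catalog(bed, format = "bed")
  expect_equal(cat_bed$tx_start[1], 1000L)  # 0-based half-open -> 1-based
  expect_equal(cat_bed$tx_end[1], 2000L)

  ann <- tempfile(); grp <- tempfile(); el <- tempfile(); gc <- tempfile()
  writeLines(c("gene_id\tsub_pathway\tpart",
               "GENEA\tcnx_crt\tupstream",
               "GENEB\tbranching_early_golgi\tdownstream"), ann)
  writeLines(c("sample_id\tpopulation\tcontinental_group",
               "I1\tp1\tEUR", "I2\tp2\tEASIA"), grp)
  writeLines(c("from\tto", "GENEA\tGENEB", "GENEB\tGENEA"), el)
  writeLines(c("gene_id\tchromosome\ttx_start\ttx_end",
               "GENEA\tchr1\t1000\t2000", "GENEB\tchr1\t5001\t6000"), gc)
  tabs <- read_tables(gc, ann, grp, el)
  # duplicate pair in both orders collapses to one undirected edge
  expect_equal(nrow(tabs$graph$edges), 1L)
  expect_s3_class(tabs$catalog, "gene_catalog")

  writeLines(c("gene_id\tsub_pathway\tpart", "GENEA\tcnx_crt\tupstrem"), ann)
  expect_error(read_tables(gc, ann, grp, el), "unknown part")
  writeLines(c("gene_id\tsub_pathway\tpart", "GENEA\tcnx_crt\tupstream"), ann)
  writeLines(c("from\tto", "GENEA\tGENEC"), el)
  expect_error(read_tables(gc, ann, grp, el), "GENEC")
  writeLines(c("gene_id\tchromosome\ttx_start\ttx_end",
               "GENEA\tchr1\t1000\t2000", "GENEA\tchr1\t5001\t6000"), gc)
  expect_error(read_gene_catalog(gc), "duplicate gene_id")
})

test_that("results TSVs round-trip exactly and are byte-stable", {
  df <- data.frame(gene_id = c("a", "b", "c"),
                   group = "EUR",
                   p = c(0.5, NA, 1e-12), stringsAsFactors = FALSE)
  d1 <- file.path(tempdir(), "out1"); d2 <- file.path(tempdir(), "out2")
  write_results_tsv(list(genes = df), d1, config = list(alpha = 0.05), seed = 9)
  write_results_tsv(list(genes = df), d2, config = list(alpha = 0.05), seed = 9)
  back <- read_results_tsv(file.path(d1, "genes.tsv"))
  expect_equal(back$p, df$p)
  expect_true(is.na(back$p[2]))
  expect_identical(readLines(file.path(d1, "genes.tsv")),
                   readLines(file.path(d2, "genes.tsv")))
  expect_identical(readLines(file.path(d1, "manifest.dcf")),
                   readLines(file.path(d2, "manifest.dcf")))
  # empty table -> header-only file
  write_results_tsv(list(empty = df[0, ]), d1)
  expect_length(readLines(file.path(d1, "empty.tsv")), 1L)
})
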