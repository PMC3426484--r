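test_that("EHH matches the hand-computed grouped count", {
  # 4 derived carriers extend right as (0,1),(0,1),(1,1),(1,0)
  hap <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(1L, 1L, 0L))
  p <- make_panel(hap)
  cv <- ehh(p, 1, "derived", "right", cutoff = 0.05)
  expect_equal(cv$points$ehh, c(1, 2 / 6, 1 / 6))
  expect_false(cv$reached_cutoff)   # chromosome ended above the cutoff
  expect_equal(cv$points$ehh[1], 1) # EHH at distance 0
  # all carriers identical over the window -> EHH stays 1
  hap2 <- rbind(c(1L, 0L, 1L), c(1L, 0L, 1L), c(1L, 0L, 1L), c(0L, 1L, 0L),
                c(0L, 0L, 1L), c(0L, 1L, 1L))
  p2 <- make_panel(hap2)
  expect_true(all(ehh(p2, 1, "derived", "right")$points$ehh == 1))
  expect_error(ehh(make_panel(rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L),
                                    c(0L, 1L))), 1, "derived", "right"),
               "too rare")
})

test_that("grouped EHH equals the pairwise-homozygosity oracle", {
  set.seed(30)
  for (rep in 1:8) {
    n_hap <- 2 * sample(5:15, 1)
    m <- sample(8:20, 1)
    hap <- matrix(rbinom(n_hap * m, 1, runif(1, 0.3, 0.7)), n_hap, m)
    core <- sample(2:(m - 1), 1)
    if (sum(hap[, core] == 1) < 2 || sum(hap[, core] == 0) < 2) next
    p <- make_panel(hap)
    for (al in c("derived", "ancestral")) {
      carriers <- which(hap[, core] == (al == "derived"))
      cv <- ehh(p, core, al, "right", cutoff = 0)
      for (k in seq_len(nrow(cv$points) - 1)) {
        expect_equal(cv$points$ehh[k + 1],
                     ehh_pairwise_oracle(hap, carriers, core, core + k),
                     tolerance = 1e-12)
      }
      # monotone non-increasing along the curve
      expect_true(all(diff(cv$points$ehh) <= 1e-12))
    }
  }
})

test_that("iHH is the trapezoidal integral with the stated properties", {
  fake <- function(pos, e, core_pos = pos[1]) {
    structure(list(core_snp_id = "s", core_position = core_pos,
                   points = data.frame(position_bp = pos, ehh = e),
                   reached_cutoff = TRUE), class = "ehh_curve")
  }
  left0 <- fake(0, 1)
  right <- fake(c(0, 1000, 2000), c(1, 0.5, 0.05))
  expect_equal(ihh(left0, right)$ihh, 750 + 275)
  # EHH identically 1 over a 10 kb side integrates to 10,000 bp
  flat <- fake(c(0, 4000, 10000), c(1, 1, 1))
  expect_equal(ihh(left0, flat)$ihh, 10000)
  # halving all distances halves iHH
  halved <- fake(c(0, 500, 1000), c(1, 0.5, 0.05))
  expect_equal(ihh(left0, halved)$ihh, 1025 / 2)
  # un-decayed side flags the edge
  flat$reached_cutoff <- FALSE
  expect_true(ihh(left0, flat)$edge)
})

test_that("unstandardized iHS is the antisymmetric log ratio", {
  expect_equal(ihs_unstandardized(5, 5), 0)
  expect_equal(ihs_unstandardized(4, 2), log(2))
  expect_equal(ihs_unstandardized(2, 4), -ihs_unstandardized(4, 2))
  expect_true(is.na(ihs_unstandardized(0, 4)))
})

test_that("standardization gives exact bin moments and matches a by-hand oracle", {
  set.seed(55)
  res <- data.frame(derived_freq = runif(400, 0.05, 0.95),
                    unstandardized = rnorm(400))
  out <- standardize_ihs(res, n_bins = 20, min_bin_count = 10)
  for (b in unique(out$freq_bin[!is.na(out$freq_bin)])) {
    x <- out$standardized[which(out$freq_bin == b)]
    expect_lt(abs(mean(x)), 1e-12)
    expect_lt(abs(sd(x) - 1), 1e-12)
  }
  expect_equal(out$abs_standardized, abs(out$standardized))

  # two-bin fixture against direct mean/sd arithmetic
  res2 <- data.frame(derived_freq = c(0.1, 0.12, 0.14, 0.8, 0.82, 0.84),
                     unstandardized = c(1, 2, 6, -1, 0, 4))
  out2 <- standardize_ihs(res2, n_bins = 2, min_bin_count = 2)
  lo <- c(1, 2, 6); hi <- c(-1, 0, 4)
  expect_equal(out2$standardized,
               c((lo - mean(lo)) / sd(lo), (hi - mean(hi)) / sd(hi)),
               tolerance = 1e-12)
  # a SNP at its bin mean standardizes to 0
  res3 <- data.frame(derived_freq = rep(0.5, 3), unstandardized = c(1, 2, 3))
  expect_equal(standardize_ihs(res3, 2, 2)$standardized[2], 0)
  # degenerate bin with zero variance errors
  res4 <- data.frame(derived_freq = rep(0.5, 12), unstandardized = rep(1, 12))
  expect_error(standardize_ihs(res4), "degenerate")
})

test_that("sparse bins merge into their nearest occupied neighbor", {
  res <- data.frame(derived_freq = c(rep(0.1, 20), rep(0.52, 3), rep(0.9, 20)),
                    unstandardized = rnorm(43))
  out <- standardize_ihs(res, n_bins = 20, min_bin_count = 10)
  # the 3-SNP middle bin cannot stand alone
  counts <- table(out$freq_bin)
  expect_true(all(counts >= 10))
  expect_equal(length(counts), 2L)
})

test_that("the scan is orientation-robust in absolute value and deterministic", {
  cfg <- sim_config(seed = 71, n_groups = 2, samples_per_group = 25,
                    n_snps = 300, chromosome_length_bp = 1.5e6,
                    wright_F = 0.05)
  p <- simulate_panel(cfg)
  sub <- subset_samples(p, 1:25)
  # 7 bins: no attainable frequency (k/50) sits exactly on a bin edge, so
  # the binning is mirror-symmetric under a global allele flip
  prm <- ihs_params(n_bins = 7, min_bin_count = 5)
  t1 <- ihs_scan(sub, params = prm)
  t2 <- ihs_scan(sub, params = prm)
  expect_identical(t1, t2)

  # globally flipping ancestral/derived flips signs but not magnitudes
  flipped <- sub
  flipped$haplotypes <- 1L - flipped$haplotypes
  t3 <- ihs_scan(flipped, params = prm)
  expect_equal(t3$value, t1$value, tolerance = 1e-9)
  expect_equal(t3$ihs_unstd, -t1$ihs_unstd, tolerance = 1e-9)
  # QC flags: edge SNPs near chromosome ends are excluded by default
  expect_true(all(t1$qc_flag %in% c("ok", "edge", "maf_range", "too_rare",
                                    "zero_ihh")))
  expect_true(all(is.na(t1$value[t1$qc_flag != "ok"])))
})

test_that("missing genotypes are rejected for iHS", {
  hap <- matrix(rbinom(80, 1, 0.5), 8, 10)
  hap[3, 4] <- NA
  expect_error(ihs_scan(make_panel(hap)), "missing-free")
})
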