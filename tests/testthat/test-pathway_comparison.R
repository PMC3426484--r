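toy_annotation <- pathway_annotation(data.frame(
  gene_id = c("U1", "U2", "U3", "D1", "D2", "S1", "X1"),
  sub_pathway = c("cnx_crt", "cnx_crt", "ost_complex", "branching_early_golgi",
                  "branching_late_golgi", "substrates", "unplaced"),
  part = c("upstream", "upstream", "upstream", "downstream", "downstream",
           "substrates", "excluded")))

toy_results <- function(sig) {
  genes <- rep(toy_annotation$gene_id, each = 2)
  data.frame(gene_id = genes, group = rep(c("EUR", "EASIA"), 7),
             statistic = "FST", significant = sig,
             stringsAsFactors = FALSE)
}

test_that("event counting is per gene, part-restricted, and >=1-group based", {
  sig <- rep(FALSE, 14)
  sig[c(1, 2)] <- TRUE   # U1 significant in both groups: one event
  sig[7] <- TRUE         # D1 in one group
  sig[11] <- TRUE        # S1 significant but substrates are excluded
  ev <- count_events_by_part(toy_results(sig), toy_annotation, "FST")
  expect_equal(ev$part, c("upstream", "downstream"))
  expect_equal(ev$n_genes, c(3L, 2L))
  expect_equal(ev$n_events, c(1L, 1L))
})

test_that("goodness-of-fit chi-square reproduces the published iHS value", {
  counts <- data.frame(part = c("upstream", "downstream"),
                       n_genes = c(25, 21), n_events = c(4, 8))
  gof <- chi2_goodness_of_fit(counts)
  expect_equal(round(gof$chi2, 2), 2.14)
  expect_equal(round(gof$p, 2), 0.14)
  expect_equal(gof$df, 1L)
  # invariant under swapping the part labels
  expect_equal(chi2_goodness_of_fit(counts[2:1, ])$chi2, gof$chi2)
  # proportional split gives 0
  prop <- data.frame(part = c("a", "b"), n_genes = c(30, 15),
                     n_events = c(4, 2))
  expect_equal(chi2_goodness_of_fit(prop)$chi2, 0)
  # random counts against an independently coded oracle
  set.seed(6)
  for (i in 1:20) {
    ng <- sample(5:40, 2)
    ne <- c(sample(0:ng[1], 1), sample(1:ng[2], 1))
    cts <- data.frame(part = c("a", "b"), n_genes = ng, n_events = ne)
    E <- ng * sum(ne) / sum(ng)
    expect_equal(chi2_goodness_of_fit(cts)$chi2, sum((ne - E)^2 / E),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney reproduces published table rows from rank structure", {
  # separated toy groups
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$rank_sum_1, 3)
  expect_equal(mw$U1, 0)
  expect_equal(mw$U, 0)
  expect_lt(mw$Z, 0)

  # U reconstruction from printed rank sums
  expect_equal(u_from_rank_sums(1485, 168, 47, 10), 113)
  expect_equal(u_from_rank_sums(1254, 399, 47, 10), 126)
  expect_equal(u_from_rank_sums(1151, 502, 40, 17), 331)

  # invariants + cross-check against wilcox.test on tie-free data
  set.seed(52)
  for (i in 1:20) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.3)
    mw <- mann_whitney(x, y)
    N <- n1 + n2
    expect_equal(mw$rank_sum_1 + mw$rank_sum_2, N * (N + 1) / 2)
    expect_equal(mw$U1 + mw$U2, n1 * n2)
    expect_equal(mw$U, min(mw$U1, mw$U2))
    wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(unname(wt$statistic), mw$U1)
    expect_equal(wt$p.value, mw$p_two_sided, tolerance = 1e-10)
  }
  expect_error(mann_whitney(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("tie correction shrinks sigma and reproduces the printed Z scale", {
  # eccentricity row of the differentiation table: tie-rich integer-like
  # centrality vectors push |Z| from 2.56 (uncorrected) toward 2.59
  x <- c(357, 235, 470)  # U1, mu, n1*n2 for n1 = 47, n2 = 10
  sigma_untied <- sqrt(470 * 58 / 12)
  expect_equal(round((x[1] - x[2]) / sigma_untied, 2), 2.56)
  set.seed(61)
  v <- sample(rep(1:8, length.out = 57))
  with_ties <- mann_whitney(v[1:47], v[48:57], tie_correction = TRUE)
  without <- mann_whitney(v[1:47], v[48:57], tie_correction = FALSE)
  expect_gt(abs(with_ties$Z), abs(without$Z) - 1e-12)
  expect_true(with_ties$tie_corrected)
})

test_that("part score comparison detects constructed separation only", {
  genes <- toy_annotation$gene_id
  res <- data.frame(gene_id = genes, group = "EUR", statistic = "FST",
                    z_fisher = c(5, 6, 7, 30, 40, 1, 1),
                    stringsAsFactors = FALSE)
  mw <- compare_part_scores(res, toy_annotation, "FST", "EUR")
  expect_equal(mw$n1, 3)  # upstream is group 1
  expect_equal(mw$n2, 2)
  expect_equal(mw$U, 0)   # downstream ranks strictly higher
  expect_equal(mw$rank_sum_1 + mw$rank_sum_2, 15)

  # identical distributions: |Z| small in most null draws
  set.seed(72)
  hi <- replicate(40, {
    r <- res
    r$z_fisher <- rnorm(7)
    abs(compare_part_scores(r, toy_annotation, "FST", "EUR")$Z)
  })
  expect_gt(mean(hi < 1.96), 0.8)
  bad <- res[res$gene_id %in% c("D1", "D2"), ]
  expect_error(compare_part_scores(bad, toy_annotation, "FST", "EUR"),
               "no scored genes")
})

test_that("hypergeometric part test matches exact summation", {
  h <- hypergeometric_part_test(25, 0, 500, 100)
  expect_equal(h$p_under, hyper_under_oracle(0, 100, 525, 25),
               tolerance = 1e-12)
  set.seed(82)
  for (i in 1:20) {
    bn <- sample(50:500, 1); be <- sample(0:bn, 1)
    pn <- sample(5:40, 1); pe <- sample(0:pn, 1)
    h <- hypergeometric_part_test(pn, pe, bn, be)
    expect_equal(h$p_under, hyper_under_oracle(pe, be + pe, bn + pn, pn),
                 tolerance = 1e-12)
    # the two tails share the observed point mass
    expect_gte(h$p_under + h$p_over, 1)
  }
  # event rate equal to the background rate: no enrichment signal
  h2 <- hypergeometric_part_test(20, 4, 480, 96)
  expect_gt(h2$p_under, 0.4)
  expect_gt(h2$p_over, 0.4)
  # observed at the maximum: p_over is the point mass at the maximum
  h3 <- hypergeometric_part_test(5, 5, 50, 20)
  expect_equal(h3$p_over, exp(lchoose(25, 5) + lchoose(30, 0) - lchoose(55, 5)),
               tolerance = 1e-12)
  expect_error(hypergeometric_part_test(10, 11, 50, 5), "exceed")
})
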