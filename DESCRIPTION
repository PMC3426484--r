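Package: pathscan
Title: Gene-Level Scans of Population Differentiation and Positive
    Selection over a Metabolic Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Selection scans for a set of pathway genes in structured
    populations. Computes per-SNP Weir-Cockerham (and Nei, Hudson) F_ST
    with one continental group contrasted against all remaining samples,
    extended haplotype homozygosity (EHH) and the integrated haplotype
    score (iHS) standardized within derived-allele-frequency bins,
    empirical p-values within bins of SNPs of similar minor allele
    frequency, Fisher-combined gene-region scores (gene +/- flank)
    calibrated against a genomic background of non-overlapping regions,
    Bonferroni-corrected significance calls, upstream-versus-downstream
    pathway comparison tests (chi-square event counts, Mann-Whitney rank
    tests, hypergeometric enrichment), and node-centrality association
    tests (betweenness, centroid, closeness, eccentricity, degree) on the
    pathway graph. Includes a Balding-Nichols haplotype simulator with
    mosaic selective sweeps so the whole pipeline is testable on
    synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
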