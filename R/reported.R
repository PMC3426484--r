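#' Published reference values for the asparagine N-glycosylation scan
#'
#' Summary tables reported for the HGDP scan of the human asparagine
#' N-glycosylation pathway (seven continental groups, F_ST and |iHS|):
#' the gene-level significance calls with raw and Bonferroni-corrected
#' p-values, the Mann-Whitney centrality-association tables, and the
#' upstream/downstream event counts. Shipped as plain TSV under
#' `inst/extdata` and used as regression fixtures for the package's
#' arithmetic (Bonferroni multiplier, U reconstruction from rank sums,
#' part-comparison chi-square).
#'
#' In the centrality tables group 1 is the genes without a significance
#' call and group 2 the significant genes; the corrected p-values in the
#' gene-hit tables carry the printed precision, so they are returned as
#' character strings.
#'
#' @param name one of `"fst_gene_hits"`, `"ihs_gene_hits"`,
#'   `"centrality_tests_fst"`, `"centrality_tests_ihs"`, `"part_events"`
#' @return the requested data frame.
#' @export
reported_table <- function(name = c("fst_gene_hits", "ihs_gene_hits",
                                    "centrality_tests_fst",
                                    "centrality_tests_ihs", "part_events")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reported_", name, ".tsv"),
                      package = "pathscan", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = if (grepl("gene_hits", name))
                            c(corrected_p = "character") else NA)
  df
}

#' Significant digits of a printed number
#'
#' Counts the significant digits in the printed representation of a
#' value (e.g. `"2.8e-23"` has 2, `"1.12e-02"` has 3), so reproduced
#' arithmetic can be compared at exactly the precision a table printed.
#'
#' @param x character vector of printed numbers
#' @return integer vector of significant-digit counts.
#' @export
printed_signif_digits <- function(x) {
  mantissa <- sub("[eE][+-]?[0-9]+$", "", x)
  digits <- gsub("[^0-9]", "", mantissa)
  digits <- sub("^0+", "", digits)
  nchar(digits)
}
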