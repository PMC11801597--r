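#' Published reference signal table for autoimmune-like hepatitis
#'
#' The 50 highest-ROR drugs from a published FAERS disproportionality
#' analysis of drug-induced autoimmune-like hepatitis (reporting window
#' 2004Q1-2024Q1, 5,723 deduplicated event reports), as printed: case
#' counts, ROR/PRR with 95% CIs, chi-square, IC with IC025, and EBGM with
#' EBGM05. Used to validate the signal classification rules against an
#' external result and to seed the default drug dictionary; the underlying
#' `b`/`d` cells are not public, so the statistics themselves cannot be
#' recomputed from it.
#'
#' @return Tibble with columns `drug`, `a`, `ror`, `ror_lo`, `ror_hi`,
#'   `prr`, `prr_lo`, `prr_hi`, `chisq`, `ic`, `ic025`, `ebgm`, `ebgm05`.
#' @export
reference_signal_table <- function() {
  path <- system.file("extdata", "dialh_reference_signals.tsv",
                      package = "pvsignal", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           comment.char = "#", check.names = FALSE)
  tab$a <- as.integer(tab$a)
  tibble::as_tibble(tab)
}

#' Published reference cohort counts for autoimmune-like hepatitis
#'
#' The clinical-characteristics table of the same published analysis:
#' per-variable level counts with the printed percentages. Sex, age,
#' reporter and country percentages are out of the 5,723 reports;
#' outcome percentages are out of all 8,018 outcome entries (outcomes are
#' multi-valued per report).
#'
#' @return Tibble with columns `variable`, `level`, `count`,
#'   `percent_printed`, `denom`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "dialh_reference_cohort.tsv",
                      package = "pvsignal", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t", quote = "",
                                      comment.char = "#",
                                      check.names = FALSE))
}
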