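#' Build per-drug 2x2 contingency tables for a target event
#'
#' For each canonical drug, counts deduplicated reports into the classic
#' pharmacovigilance 2x2 cells against the rest of the database:
#' `a` = reports with drug and target event, `b` = drug without event,
#' `c` = event without drug, `d` = neither. Counting is report-level: a
#' report with several mentions of the same drug contributes once, and the
#' comparator is the whole deduplicated report set (`N = a + b + c + d`).
#'
#' @param reports Deduplicated report tibble ([deduplicate_reports()]).
#' @param drugs Drug-mention tibble with a `normalized_name` column
#'   ([normalize_mentions()]); unresolved mentions (`NA`) are excluded.
#' @param event_ids Character vector of `primaryid`s reporting the target
#'   event ([filter_event()]).
#' @param roles FAERS role codes counted as exposure. The default counts
#'   suspect drugs only (primary and secondary suspect).
#' @return Tibble with columns `drug`, `a`, `b`, `c`, `d`, `N`, one row
#'   per drug with at least one qualifying mention.
#' @export
build_contingency <- function(reports, drugs, event_ids,
                              roles = c("PS", "SS")) {
  stopifnot(all(roles %in% c("PS", "SS", "C", "I")))
  if (nrow(reports) == 0) {
    warning("build_contingency: empty report set", call. = FALSE)
    return(tibble::tibble(drug = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), N = integer()))
  }
  if (!"normalized_name" %in% names(drugs)) {
    stop("drug mentions must be normalized first (normalize_mentions)",
         call. = FALSE)
  }
  N <- nrow(reports)
  ids <- reports$primaryid
  event_ids <- intersect(event_ids, ids)
  n_event <- length(event_ids)

  mentions <- drugs |>
    dplyr::filter(!is.na(.data$normalized_name),
                  .data$role %in% roles,
                  .data$primaryid %in% ids) |>
    dplyr::distinct(.data$normalized_name, .data$primaryid)

  mentions |>
    dplyr::group_by(drug = .data$normalized_name) |>
    dplyr::summarise(
      a = sum(.data$primaryid %in% event_ids),
      b = dplyr::n() - .data$a,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      c = n_event - .data$a,
      d = N - .data$a - .data$b - .data$c,
      N = N,
      dplyr::across(c("a", "b", "c", "d", "N"), as.integer)
    ) |>
    dplyr::arrange(.data$drug)
}

#' Drop drugs below a minimum case count
#'
#' Disproportionality statistics on fewer than a handful of co-reports are
#' unstable; the conventional screen keeps drugs with at least three
#' target-event reports.
#'
#' @param tables Contingency tibble from [build_contingency()].
#' @param threshold Minimum value of `a` (default 3).
#' @return The filtered tibble.
#' @export
min_case_filter <- function(tables, threshold = 3) {
  stopifnot(threshold >= 1)
  keep <- tables$a >= threshold
  if (any(!keep)) {
    message("min_case_filter: removed ", sum(!keep), " drug(s) with a < ",
            threshold)
  }
  tables[keep, , drop = FALSE]
}
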