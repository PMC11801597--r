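#' Percentage of a count, rounded half-up to two decimals
#'
#' The display convention of descriptive cohort tables: `100 * count /
#' denom`, with trailing-5 values rounded away from zero.
#'
#' @param count Non-negative integer vector, `count <= denom`.
#' @param denom Positive denominator.
#' @return Numeric percentages at two decimal places.
#' @examples
#' percent_of(1490, 5723)  # 26.04
#' @export
percent_of <- function(count, denom) {
  if (any(denom <= 0)) {
    stop("undefined result: zero or negative denominator", call. = FALSE)
  }
  if (any(count < 0 | count > denom)) {
    stop("count must lie in [0, denom]", call. = FALSE)
  }
  round_half_up(100 * count / denom, 2)
}

count_table <- function(x, levels, denom) {
  x <- factor(x, levels = levels)
  tab <- table(x)
  tibble::tibble(level = names(tab), count = as.integer(tab),
                 percent = percent_of(as.integer(tab), denom))
}

quartile_row <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(x), median = round_half_up(q[2], 2),
                 q1 = round_half_up(q[1], 2), q3 = round_half_up(q[3], 2))
}

age_bin_labels <- function(cuts) {
  lo <- c(NA, cuts)
  hi <- c(cuts, NA)
  labs <- character(length(lo))
  labs[1] <- paste0("<", cuts[1])
  labs[length(labs)] <- paste0(">=", cuts[length(cuts)])
  if (length(cuts) > 1) {
    labs[2:(length(labs) - 1)] <-
      paste0(cuts[-length(cuts)], "~", cuts[-1])
  }
  labs
}

#' Descriptive summary of an event cohort
#'
#' Produces the standard clinical-characteristics breakdown of a set of
#' deduplicated case reports: sex, age strata, reporter occupation,
#' reporting country (top countries kept verbatim, the rest grouped as
#' "other"), outcome distribution, medians with quartiles for age, weight
#' and (when present) time to onset, and yearly report counts.
#'
#' Age bins are left-closed, right-open (`[lo, hi)`), with the last bin
#' unbounded above; a report with exactly the boundary age falls in the
#' higher bin. Missing values form an explicit "unknown" level and count
#' towards the denominator `N`; medians and quartiles use non-missing
#' values only (type-7 linear-interpolation quantiles). Outcomes are
#' multi-valued per report, so outcome percentages use the total number of
#' outcome entries as denominator, not `N`.
#'
#' @param reports Deduplicated report tibble; an optional `tto_days`
#'   column (see [time_to_onset()]) adds a time-to-onset row.
#' @param age_cuts Ordered interior cut points in years.
#' @param top_countries Number of most frequent countries kept verbatim.
#' @return A list of class `pv_cohort`: `n`, tibbles `sex`, `age`,
#'   `reporter`, `country`, `outcomes`, `yearly_counts`, and quartile rows
#'   `age_summary`, `weight_summary`, `tto_summary`.
#' @export
summarize_cohort <- function(reports, age_cuts = c(19, 45, 65, 75),
                             top_countries = 5) {
  n <- nrow(reports)
  stopifnot(n > 0)

  sex <- count_table(
    ifelse(reports$sex %in% c("female", "male"), reports$sex, "unknown"),
    c("female", "male", "unknown"), n)

  labs <- age_bin_labels(age_cuts)
  bin <- cut(reports$age_years, breaks = c(-Inf, age_cuts, Inf),
             labels = labs, right = FALSE)
  bin <- as.character(bin)
  bin[is.na(bin)] <- "unknown"
  age <- count_table(bin, c(labs, "unknown"), n)

  occ_levels <- c("Physician", "Other health-professional", "Consumer",
                  "Pharmacist", "Lawyer", "Registered Nurse", "unknown")
  reporter <- count_table(
    ifelse(reports$reporter_occupation %in% occ_levels,
           reports$reporter_occupation, "unknown"),
    occ_levels, n)

  cn <- reports$reporter_country
  known <- cn[cn != "unknown"]
  top <- names(sort(table(known), decreasing = TRUE))
  top <- utils::head(top, top_countries)
  cn_grp <- ifelse(cn %in% top, cn, "other")
  country <- count_table(cn_grp, c(top, "other"), n)

  outc <- if ("outcomes" %in% names(reports)) {
    unlist(reports$outcomes, use.names = FALSE)
  } else {
    character()
  }
  outcome_levels <- unname(outcome_code_map)
  outcomes <- if (length(outc) > 0) {
    count_table(outc, outcome_levels, length(outc))
  } else {
    tibble::tibble(level = outcome_levels, count = 0L, percent = NA_real_)
  }

  yr <- as.integer(format(reports$fda_receipt_date, "%Y"))
  yearly <- tibble::tibble(year = yr[!is.na(yr)]) |>
    dplyr::count(.data$year, name = "count") |>
    dplyr::arrange(.data$year)

  structure(
    list(
      n = n, sex = sex, age = age, reporter = reporter, country = country,
      outcomes = outcomes, yearly_counts = yearly,
      age_summary = quartile_row(reports$age_years),
      weight_summary = quartile_row(reports$weight_kg),
      tto_summary = if ("tto_days" %in% names(reports)) {
        quartile_row(reports$tto_days)
      } else {
        quartile_row(numeric())
      }
    ),
    class = "pv_cohort"
  )
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat("Event cohort summary:", x$n, "deduplicated reports\n")
  cat(sprintf("  median age %s years (Q1 %s, Q3 %s; n=%d known)\n",
              x$age_summary$median, x$age_summary$q1, x$age_summary$q3,
              x$age_summary$n))
  for (nm in c("sex", "age", "reporter", "country", "outcomes")) {
    cat("--", nm, "--\n")
    print(as.data.frame(x[[nm]]), row.names = FALSE)
  }
  cat("-- yearly counts --\n")
  print(as.data.frame(x$yearly_counts), row.names = FALSE)
  invisible(x)
}

#' Time from first suspect-drug administration to event onset
#'
#' Joins therapy start dates to suspect-drug mentions (on report and drug
#' sequence when available) and returns, per report, the days from the
#' earliest suspect-drug start date to the event date. Negative intervals
#' and intervals over 20 years are treated as data errors and set to
#' missing.
#'
#' @param reports Report tibble with `primaryid` and `event_date`.
#' @param drugs Drug-mention tibble with `primaryid`, `drug_seq`, `role`.
#' @param therapy Therapy tibble with `primaryid`, `drug_seq`,
#'   `start_date`.
#' @param roles Roles counted as suspect (default PS and SS).
#' @return Tibble `primaryid`, `tto_days` (NA where undefined).
#' @export
time_to_onset <- function(reports, drugs, therapy,
                          roles = c("PS", "SS")) {
  suspects <- drugs[drugs$role %in% roles,
                    c("primaryid", "drug_seq"), drop = FALSE]
  use_seq <- !all(is.na(suspects$drug_seq)) &&
    !all(is.na(therapy$drug_seq))
  joined <- if (use_seq) {
    dplyr::inner_join(suspects, therapy,
                      by = c("primaryid", "drug_seq"))
  } else {
    dplyr::inner_join(suspects, therapy[, c("primaryid", "start_date")],
                      by = "primaryid", relationship = "many-to-many")
  }
  starts <- joined |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_date = min(.data$start_date), .groups = "drop")
  out <- dplyr::left_join(reports[, c("primaryid", "event_date")], starts,
                          by = "primaryid")
  tto <- as.numeric(out$event_date - out$start_date)
  tto[!is.na(tto) & (tto < 0 | tto > 20 * 365.25)] <- NA_real_
  tibble::tibble(primaryid = out$primaryid, tto_days = tto)
}

#' Bar chart of yearly report counts
#'
#' @param cohort A `pv_cohort` object from [summarize_cohort()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_yearly_counts <- function(cohort) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_yearly_counts requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(cohort$yearly_counts,
                  ggplot2::aes(x = .data$year, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Year of receipt", y = "Reports",
                  title = "Event reports per year") +
    ggplot2::theme_minimal()
}
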