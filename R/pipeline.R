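#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: input location (either
#' FAERS-format file paths or an in-memory `faers_data` list), the target
#' Preferred Term, the receipt-date window, drug roles counted as
#' exposure, signal thresholds and ranking depth.
#'
#' @param quarters List of per-quarter path lists (each with `demo`,
#'   `drug`, `reac`, optionally `outc`, `ther`) or a single such list.
#'   Ignored when `dataset` is supplied.
#' @param dataset An in-memory `faers_data` list (see
#'   [read_faers_quarter()]); alternative to `quarters`.
#' @param layout FAERS file layout for `quarters`.
#' @param dictionary A `drug_dictionary`; defaults to the shipped one.
#' @param target_pt Target MedDRA Preferred Term.
#' @param window `NULL` or two dates bounding `fda_receipt_date`.
#' @param roles Drug role codes counted as exposure.
#' @param thresholds A [pv_thresholds()] object.
#' @param min_cases Minimum target-event reports per drug retained.
#' @param top_n Depth of the ranked signal table.
#' @param rank_by `"ror"` (signal strength, default) or `"cases"`
#'   (reporting frequency).
#' @param out_dir If non-`NULL`, TSV outputs are written there.
#' @return A list of class `pv_config`.
#' @export
pv_config <- function(quarters = NULL, dataset = NULL,
                      layout = c("modern", "legacy"),
                      dictionary = read_drug_dictionary(),
                      target_pt = "autoimmune hepatitis",
                      window = NULL, roles = c("PS", "SS"),
                      thresholds = pv_thresholds(), min_cases = 3,
                      top_n = 50, rank_by = c("ror", "cases"),
                      out_dir = NULL) {
  layout <- match.arg(layout)
  rank_by <- match.arg(rank_by)
  if (is.null(quarters) && is.null(dataset)) {
    stop("pv_config: supply either quarters (file paths) or dataset",
         call. = FALSE)
  }
  if (!is.null(quarters) && !is.null(quarters$demo)) {
    quarters <- list(quarters)  # single quarter supplied flat
  }
  if (!is.null(window)) {
    window <- as.Date(window)
    stopifnot(length(window) == 2, window[1] <= window[2])
  }
  stopifnot(top_n >= 1)
  structure(
    list(quarters = quarters, dataset = dataset, layout = layout,
         dictionary = dictionary, target_pt = target_pt, window = window,
         roles = roles, thresholds = thresholds, min_cases = min_cases,
         top_n = top_n, rank_by = rank_by, out_dir = out_dir),
    class = "pv_config"
  )
}

bind_faers <- function(datasets) {
  parts <- c("reports", "drugs", "reactions", "outcomes", "therapy")
  out <- lapply(parts, function(p) {
    dplyr::bind_rows(lapply(datasets, `[[`, p))
  })
  names(out) <- parts
  structure(out, class = "faers_data")
}

#' Run the full signal-detection pipeline
#'
#' Ingest (one quarter at a time) -> case deduplication -> optional
#' receipt-window restriction -> drug-name normalization -> target-event
#' retrieval -> per-drug 2x2 tables -> minimum-case screen -> four
#' disproportionality statistics -> threshold classification -> ranked
#' signal table, plus the descriptive cohort summary of the event
#' reports. Row counts are logged at every stage. With identical inputs
#' and configuration the output is identical across runs.
#'
#' @param config A [pv_config()] object.
#' @return A list of class `pv_report`: `cohort` (a `pv_cohort` for the
#'   target-event reports), `signals` (full classified signal tibble,
#'   ranked), `top` (its first `top_n` rows), `coverage` (dictionary
#'   coverage of the drug mentions), `n_reports`, `n_event`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_config"))
  data <- if (!is.null(config$dataset)) {
    config$dataset
  } else {
    bind_faers(lapply(config$quarters, read_faers_quarter,
                      layout = config$layout))
  }
  message("pipeline: ", nrow(data$reports), " raw report rows")

  reports <- deduplicate_reports(data$reports)
  if (!is.null(config$window)) {
    reports <- filter_window(reports, config$window[1], config$window[2])
  }
  message("pipeline: ", nrow(reports), " deduplicated in-window reports")

  drugs <- normalize_mentions(data$drugs, config$dictionary)
  coverage <- coverage_report(drugs, config$dictionary)
  event_ids <- filter_event(data$reactions, config$target_pt)
  event_ids <- intersect(event_ids, reports$primaryid)
  message("pipeline: ", length(event_ids), " target-event reports")
  if (length(event_ids) == 0) {
    warning("no reports contain the target term '", config$target_pt,
            "'", call. = FALSE)
  }

  tables <- build_contingency(reports, drugs, event_ids,
                              roles = config$roles)
  tables <- min_case_filter(tables, config$min_cases)
  message("pipeline: ", nrow(tables), " drugs at or above the ",
          config$min_cases, "-case screen")

  signals <- signal_stats(tables)
  signals <- classify_signals(signals, config$thresholds)
  signals <- rank_signals(signals, top_n = Inf, by = config$rank_by)
  top <- utils::head(signals, config$top_n)

  event_reports <- reports[reports$primaryid %in% event_ids, ,
                           drop = FALSE]
  cohort <- if (nrow(event_reports) > 0) {
    tto <- time_to_onset(event_reports, data$drugs, data$therapy,
                         roles = config$roles)
    event_reports$tto_days <-
      tto$tto_days[match(event_reports$primaryid, tto$primaryid)]
    summarize_cohort(event_reports)
  }

  out <- structure(
    list(cohort = cohort, signals = signals, top = top,
         coverage = coverage, n_reports = nrow(reports),
         n_event = length(event_ids)),
    class = "pv_report"
  )
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' Write pipeline outputs as TSV files
#'
#' Emits `signals.tsv` (fixed column order), `top_signals.tsv`,
#' `cohort_summary.tsv` and `yearly_counts.tsv`.
#'
#' @param report A `pv_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_cols <- c("drug", "a", "ror", "ror_lo", "ror_hi", "prr", "prr_lo",
                "prr_hi", "chisq", "ic", "ic025", "ebgm", "ebgm05",
                "ror_pos", "prr_pos", "bcpnn_pos", "ebgm_pos",
                "consensus")
  paths <- character()
  fmt <- function(x) {
    num <- vapply(x, is.numeric, logical(1)) & names(x) != "a"
    x[num] <- lapply(x[num], round_half_up, digits = 2)
    x
  }
  sig <- fmt(report$signals[, sig_cols])
  p <- file.path(dir, "signals.tsv")
  data.table::fwrite(sig, p, sep = "\t", quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "top_signals.tsv")
  data.table::fwrite(fmt(report$top[, sig_cols]), p, sep = "\t",
                     quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$cohort)) {
    co <- report$cohort
    rows <- dplyr::bind_rows(
      dplyr::mutate(co$sex, variable = "sex"),
      dplyr::mutate(co$age, variable = "age"),
      dplyr::mutate(co$reporter, variable = "reporter"),
      dplyr::mutate(co$country, variable = "country"),
      dplyr::mutate(co$outcomes, variable = "outcome")
    )[, c("variable", "level", "count", "percent")]
    p <- file.path(dir, "cohort_summary.tsv")
    data.table::fwrite(rows, p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "yearly_counts.tsv")
    data.table::fwrite(co$yearly_counts, p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @export
print.pv_report <- function(x, ...) {
  cat("pvsignal report:", x$n_reports, "deduplicated reports,",
      x$n_event, "with the target event\n")
  cat("Top signals (by", if (nrow(x$top) > 0) "ranking):" else ":", "\n")
  show <- utils::head(x$top, 10)
  if (nrow(show) > 0) {
    cols <- c("drug", "a", "ror", "ror_lo", "ror_hi", "ic025", "ebgm05",
              "consensus")
    df <- as.data.frame(show[, cols])
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "a"
    df[num] <- lapply(df[num], round_half_up, digits = 2)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
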