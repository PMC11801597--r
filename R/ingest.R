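#' @importFrom rlang .data
NULL

# Column dialects for the two eras of FAERS quarterly extracts. Legacy
# (pre-2012Q4) files are ISR-keyed and carry no case version; modern files
# are primaryid-keyed. Each entry gives the mandatory columns for the
# declared layout -- a missing mandatory column is a schema error.
faers_layouts <- list(
  modern = list(
    key = "primaryid",
    demo = list(mandatory = c("primaryid", "caseid", "fda_dt"),
                optional  = c("caseversion", "event_dt", "age", "age_cod",
                              "sex", "wt", "wt_cod", "occp_cod",
                              "occr_country")),
    drug = list(mandatory = c("primaryid", "drugname", "role_cod"),
                optional  = "drug_seq"),
    reac = list(mandatory = c("primaryid", "pt"), optional = character()),
    outc = list(mandatory = c("primaryid", "outc_cod"), optional = character()),
    ther = list(mandatory = c("primaryid", "start_dt"),
                optional  = "dsg_drug_seq")
  ),
  legacy = list(
    key = "isr",
    demo = list(mandatory = c("isr", "case", "fda_dt"),
                optional  = c("event_dt", "age", "age_cod", "gndr_cod",
                              "wt", "wt_cod", "occp_cod",
                              "reporter_country")),
    drug = list(mandatory = c("isr", "drugname", "role_cod"),
                optional  = "drug_seq"),
    reac = list(mandatory = c("isr", "pt"), optional = character()),
    outc = list(mandatory = c("isr", "outc_cod"), optional = character()),
    ther = list(mandatory = c("isr", "start_dt"), optional = "drug_seq")
  )
)

outcome_code_map <- c(
  OT = "other serious", HO = "hospitalization", DE = "death",
  LT = "life threatening", DS = "disability",
  RI = "required intervention", CA = "congenital anomaly"
)

occupation_code_map <- c(
  MD = "Physician", PH = "Pharmacist", OT = "Other health-professional",
  HP = "Other health-professional", CN = "Consumer", LW = "Lawyer",
  RN = "Registered Nurse"
)

read_faers_table <- function(path, cols, table_name) {
  if (!file.exists(path)) {
    stop("file not found for ", table_name, " table: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    warning("empty ", table_name, " file: ", path, call. = FALSE)
    cols <- c(cols$mandatory, cols$optional)
    out <- stats::setNames(
      rep(list(character()), length(cols)), cols)
    return(tibble::as_tibble(out))
  }
  dt <- data.table::fread(path, sep = "$", quote = "", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = FALSE, showProgress = FALSE)
  names(dt) <- tolower(names(dt))
  missing <- setdiff(cols$mandatory, names(dt))
  if (length(missing) > 0) {
    stop("schema error in ", table_name, " table (", basename(path),
         "): missing mandatory column '", missing[[1]], "'", call. = FALSE)
  }
  for (col in setdiff(cols$optional, names(dt))) dt[[col]] <- NA_character_
  tibble::as_tibble(dt[, c(cols$mandatory, cols$optional), drop = FALSE])
}

#' Read one quarter of FAERS ASCII tables
#'
#' Parses the dollar-delimited DEMO/DRUG/REAC (and optionally OUTC/THER)
#' files of a single quarterly extract into the package's internal case
#' model. Unparseable dates and ages become missing values; no row is ever
#' dropped at parse time. Legacy (ISR-keyed) extracts are harmonized to the
#' modern keys, with `case_version` 0.
#'
#' @param paths Named list or character vector of file paths with elements
#'   `demo`, `drug`, `reac` and optionally `outc`, `ther`.
#' @param layout `"modern"` (primaryid-keyed, 2012Q4 onwards) or `"legacy"`
#'   (ISR-keyed).
#' @return A list of class `faers_data` with tibbles:
#' \describe{
#'   \item{reports}{one row per DEMO record: `primaryid`, `caseid`,
#'     `case_version`, `fda_receipt_date`, `event_date`, `sex`,
#'     `age_value`, `age_unit`, `age_years`, `weight_kg`,
#'     `reporter_occupation`, `reporter_country`, and an `outcomes`
#'     list-column when an OUTC file is supplied.}
#'   \item{drugs}{per-report drug mentions: `primaryid`, `drug_seq`,
#'     `raw_name`, `role` (PS/SS/C/I).}
#'   \item{reactions}{per-report MedDRA Preferred Terms: `primaryid`, `pt`.}
#'   \item{outcomes}{per-report outcome labels (possibly empty tibble).}
#'   \item{therapy}{therapy start dates: `primaryid`, `drug_seq`,
#'     `start_date`.}
#' }
#' @seealso [deduplicate_reports()], [filter_event()], [write_faers_quarter()]
#' @export
read_faers_quarter <- function(paths, layout = c("modern", "legacy")) {
  layout <- match.arg(layout)
  lay <- faers_layouts[[layout]]
  paths <- as.list(paths)
  for (req in c("demo", "drug", "reac")) {
    if (is.null(paths[[req]])) {
      stop("paths must include a '", req, "' file", call. = FALSE)
    }
  }
  key <- lay$key

  demo <- read_faers_table(paths$demo, lay$demo, "DEMO")
  drug <- read_faers_table(paths$drug, lay$drug, "DRUG")
  reac <- read_faers_table(paths$reac, lay$reac, "REAC")
  outc <- if (!is.null(paths$outc)) {
    read_faers_table(paths$outc, lay$outc, "OUTC")
  }
  ther <- if (!is.null(paths$ther)) {
    read_faers_table(paths$ther, lay$ther, "THER")
  }

  sex_raw <- if (layout == "modern") demo$sex else demo$gndr_cod
  country <- if (layout == "modern") demo$occr_country else demo$reporter_country
  fda_date <- parse_faers_date(demo$fda_dt)
  n_bad_dates <- sum(is.na(fda_date) & nzchar(trimws(demo$fda_dt)))

  reports <- tibble::tibble(
    primaryid = trimws(demo[[key]]),
    caseid = trimws(if (layout == "modern") demo$caseid else demo$case),
    case_version = if (layout == "modern") {
      v <- suppressWarnings(as.integer(demo$caseversion))
      ifelse(is.na(v), 0L, v)
    } else {
      rep(0L, nrow(demo))
    },
    fda_receipt_date = fda_date,
    event_date = parse_faers_date(demo$event_dt),
    sex = dplyr::case_match(toupper(trimws(sex_raw)),
                            "F" ~ "female", "M" ~ "male",
                            .default = "unknown"),
    age_value = suppressWarnings(as.numeric(demo$age)),
    age_unit = toupper(trimws(demo$age_cod)),
    age_years = age_to_years(demo$age, demo$age_cod),
    weight_kg = {
      w <- suppressWarnings(as.numeric(demo$wt))
      w <- ifelse(!is.na(w) & toupper(trimws(demo$wt_cod)) %in% c("LBS", "LB"),
                  w * 0.453592, w)
      ifelse(!is.na(w) & w <= 0, NA_real_, w)
    },
    reporter_occupation = {
      occ <- unname(occupation_code_map[toupper(trimws(demo$occp_cod))])
      ifelse(is.na(occ), "unknown", occ)
    },
    reporter_country = {
      cn <- trimws(country)
      ifelse(is.na(cn) | !nzchar(cn), "unknown", cn)
    }
  )

  drugs <- tibble::tibble(
    primaryid = trimws(drug[[key]]),
    drug_seq = suppressWarnings(as.integer(drug$drug_seq)),
    raw_name = trimws(drug$drugname),
    role = toupper(trimws(drug$role_cod))
  )
  bad_roles <- !drugs$role %in% c("PS", "SS", "C", "I")
  drugs$role[bad_roles] <- NA_character_

  reactions <- tibble::tibble(
    primaryid = trimws(reac[[key]]),
    pt = trimws(reac$pt)
  )
  reactions <- dplyr::filter(reactions, nzchar(.data$pt))

  outcomes <- if (!is.null(outc)) {
    oc <- outcome_code_map[toupper(trimws(outc$outc_cod))]
    dplyr::distinct(tibble::tibble(
      primaryid = trimws(outc[[key]]),
      outcome = ifelse(is.na(oc), "other serious", unname(oc))
    ))
  } else {
    tibble::tibble(primaryid = character(), outcome = character())
  }

  therapy <- if (!is.null(ther)) {
    seq_col <- if (layout == "modern") ther$dsg_drug_seq else ther$drug_seq
    tibble::tibble(
      primaryid = trimws(ther[[key]]),
      drug_seq = suppressWarnings(as.integer(seq_col)),
      start_date = parse_faers_date(ther$start_dt)
    )
  } else {
    tibble::tibble(primaryid = character(), drug_seq = integer(),
                   start_date = as.Date(character()))
  }

  # attach outcome sets (sorted, unique) to the report rows
  if (nrow(outcomes) > 0) {
    sets <- split(outcomes$outcome, outcomes$primaryid)
    sets <- lapply(sets, function(x) sort(unique(x)))
    reports$outcomes <- unname(sets[reports$primaryid])
    reports$outcomes[vapply(reports$outcomes, is.null, logical(1))] <-
      list(character())
  } else {
    reports$outcomes <- rep(list(character()), nrow(reports))
  }

  message(sprintf(
    "read_faers_quarter [%s]: %d reports, %d drug mentions, %d reactions (%d unparseable receipt dates set missing)",
    layout, nrow(reports), nrow(drugs), nrow(reactions), n_bad_dates))

  structure(
    list(reports = reports, drugs = drugs, reactions = reactions,
         outcomes = outcomes, therapy = therapy),
    class = "faers_data"
  )
}

#' Write the internal case model back to FAERS ASCII files
#'
#' Emits the modern dollar-delimited dialect (DEMO.txt, DRUG.txt, REAC.txt,
#' OUTC.txt, THER.txt). Re-reading the written files with
#' [read_faers_quarter()] reproduces the parsed field values.
#'
#' @param data A `faers_data` list as returned by [read_faers_quarter()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_faers_quarter <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- data$reports
  sex_back <- dplyr::case_match(r$sex, "female" ~ "F", "male" ~ "M",
                                .default = "")
  occ_back <- names(occupation_code_map)[
    match(r$reporter_occupation, occupation_code_map)]
  occ_back[is.na(occ_back)] <- ""
  demo <- data.frame(
    primaryid = r$primaryid, caseid = r$caseid,
    caseversion = r$case_version,
    event_dt = format_faers_date(r$event_date),
    fda_dt = format_faers_date(r$fda_receipt_date),
    age = ifelse(is.na(r$age_value), "", as.character(r$age_value)),
    age_cod = ifelse(is.na(r$age_unit), "", r$age_unit),
    sex = sex_back,
    wt = ifelse(is.na(r$weight_kg), "", as.character(r$weight_kg)),
    wt_cod = ifelse(is.na(r$weight_kg), "", "KG"),
    occp_cod = occ_back,
    occr_country = ifelse(r$reporter_country == "unknown", "",
                          r$reporter_country),
    check.names = FALSE
  )
  d <- data$drugs
  drug <- data.frame(
    primaryid = d$primaryid,
    drug_seq = ifelse(is.na(d$drug_seq), "", as.character(d$drug_seq)),
    role_cod = ifelse(is.na(d$role), "", d$role),
    drugname = d$raw_name
  )
  reac <- data.frame(primaryid = data$reactions$primaryid,
                     pt = data$reactions$pt)
  oc_back <- names(outcome_code_map)[
    match(data$outcomes$outcome, outcome_code_map)]
  outc <- data.frame(primaryid = data$outcomes$primaryid,
                     outc_cod = ifelse(is.na(oc_back), "OT", oc_back))
  th <- data$therapy
  ther <- data.frame(
    primaryid = th$primaryid,
    dsg_drug_seq = ifelse(is.na(th$drug_seq), "", as.character(th$drug_seq)),
    start_dt = format_faers_date(th$start_date)
  )
  files <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             outc = file.path(dir, "OUTC.txt"),
             ther = file.path(dir, "THER.txt"))
  tables <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther)
  for (nm in names(files)) {
    data.table::fwrite(tables[[nm]], files[[nm]], sep = "$", quote = FALSE)
  }
  invisible(files)
}

#' Deduplicate case reports to one row per case
#'
#' FAERS cases accumulate versions as follow-up reports arrive; only the
#' most recent version should enter analysis. For each `caseid` the row
#' with the highest (`case_version`, `fda_receipt_date`, `primaryid`)
#' lexicographic key is kept. `primaryid` is compared numerically when all
#' ids are numeric.
#'
#' @param reports Tibble of case reports (see [read_faers_quarter()]).
#' @return The deduplicated tibble, one row per `caseid`.
#' @export
deduplicate_reports <- function(reports) {
  if (nrow(reports) == 0) return(reports)
  reports <- dplyr::distinct(reports, .data$primaryid, .keep_all = TRUE)
  pid_num <- suppressWarnings(as.numeric(reports$primaryid))
  pid_key <- if (anyNA(pid_num)) xtfrm(reports$primaryid) else pid_num
  ord <- order(reports$caseid, reports$case_version,
               reports$fda_receipt_date, pid_key, na.last = FALSE)
  reports <- reports[ord, , drop = FALSE]
  keep <- !duplicated(reports$caseid, fromLast = TRUE)
  removed <- sum(!keep)
  if (removed > 0) {
    message("deduplicate_reports: removed ", removed,
            " superseded case version(s)")
  }
  reports[keep, , drop = FALSE]
}

#' Identify reports containing a target Preferred Term
#'
#' Matching is exact after case folding and whitespace normalization; no
#' MedDRA hierarchy traversal is attempted.
#'
#' @param reactions Tibble with columns `primaryid`, `pt`.
#' @param target_pt The target MedDRA Preferred Term string.
#' @return Character vector of unique `primaryid`s reporting the term.
#' @export
filter_event <- function(reactions, target_pt) {
  stopifnot(is.character(target_pt), length(target_pt) == 1,
            nzchar(trimws(target_pt)))
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  unique(reactions$primaryid[norm(reactions$pt) == norm(target_pt)])
}

#' Restrict reports to a receipt-date window
#'
#' Membership is decided on `fda_receipt_date` (inclusive bounds); field
#' values are never altered.
#'
#' @param reports Tibble of case reports.
#' @param start,end `Date` (or coercible) bounds; `NULL` leaves that side
#'   open.
#' @return The filtered tibble.
#' @export
filter_window <- function(reports, start = NULL, end = NULL) {
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(start)) {
    keep <- keep & !is.na(reports$fda_receipt_date) &
      reports$fda_receipt_date >= as.Date(start)
  }
  if (!is.null(end)) {
    keep <- keep & !is.na(reports$fda_receipt_date) &
      reports$fda_receipt_date <= as.Date(end)
  }
  reports[keep, , drop = FALSE]
}
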