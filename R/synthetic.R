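# Synthetic spontaneous-report generator with known ground truth.
#
# Emulates the joint structure of a FAERS quarter -- one demographic row
# per case version, many drug mentions and reaction PTs per report,
# multi-valued outcomes -- with configurable planted drug-event relative
# risks, so every pipeline stage can be validated without the real
# database.

#' Default synthetic drug catalog
#'
#' Drugs with known hepatitis signals (seeding the shipped
#' dictionary) padded with invented background compounds, with marginal
#' reporting probabilities decaying geometrically from `p_max` to `p_min`.
#'
#' @param n_drugs Catalog size (default 100).
#' @param p_max,p_min Largest and smallest per-report mention probability.
#' @return Tibble with columns `label`, `prob`.
#' @export
default_drug_catalog <- function(n_drugs = 100, p_max = 0.05,
                                 p_min = 0.005) {
  known <- reference_signal_table()$drug
  extra_needed <- max(0, n_drugs - length(known))
  synth <- character(extra_needed)
  if (extra_needed > 0) {
    combos <- expand.grid(a = letters, b = letters,
                          stringsAsFactors = FALSE)
    synth <- paste0("synthdrug", combos$a, combos$b)[seq_len(extra_needed)]
  }
  labels <- c(known, synth)[seq_len(n_drugs)]
  probs <- p_max * (p_min / p_max)^(seq(0, 1, length.out = n_drugs))
  tibble::tibble(label = labels, prob = probs)
}

default_demographics <- function() {
  list(
    sex = c(female = 0.611, male = 0.287, unknown = 0.102),
    # age strata probabilities mirror a typical hepatitis event cohort;
    # the remainder is missing age
    age_strata = c("0-19" = 0.0425, "19-45" = 0.1746, "45-65" = 0.3250,
                   "65-75" = 0.1470, "75-95" = 0.0825),
    weight_meanlog = log(70), weight_sdlog = 0.27, weight_known = 0.4,
    country = c("United States" = 0.2604, "Germany" = 0.0692,
                "Japan" = 0.0561, "France" = 0.0556,
                "United Kingdom" = 0.0467, "Canada" = 0.15,
                "Italy" = 0.12, "Spain" = 0.10, "Brazil" = 0.092,
                "Australia" = 0.05),
    occupation = stats::setNames(
      c(0.4403, 0.2015, 0.1569, 0.1499, 0.0465, 0.0047, 0.0002),
      c("MD", "OT", "CN", "PH", "", "LW", "RN")),
    outcome = c(OT = 0.5438, HO = 0.3209, DE = 0.0559, LT = 0.0504,
                DS = 0.0232, RI = 0.0055, CA = 0.0004),
    tto_meanlog = log(86), tto_sdlog = 1.2, event_date_known = 0.8
  )
}

#' Configuration for the synthetic report generator
#'
#' @param n_reports Number of cases to generate.
#' @param drug_catalog Tibble `label`, `prob`: per-report marginal mention
#'   probability of each drug (drawn independently).
#' @param target_pt The target event Preferred Term written to REAC rows.
#' @param background_event_rate Event probability for a report exposed to
#'   no elevated-risk drug.
#' @param planted_effects Tibble `drug`, `lambda`: planted relative risks
#'   (`lambda >= 1`). A report's event probability is
#'   `background_event_rate * max(lambda over mentioned drugs)`, capped at
#'   1; the max keeps lambda interpretable as a per-drug risk ratio when
#'   exposures overlap.
#' @param demographics List of category probabilities for sex, age
#'   strata, weight, country, reporter occupation and outcomes (see
#'   `default_demographics`).
#' @param window Character vector of two dates bounding receipt dates.
#' @param seed Integer RNG seed; the whole generation is a deterministic
#'   function of the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_reports,
                         drug_catalog = default_drug_catalog(),
                         target_pt = "Autoimmune hepatitis",
                         background_event_rate = 0.005,
                         planted_effects = NULL,
                         demographics = default_demographics(),
                         window = c("2004-01-01", "2024-03-31"),
                         seed = 1) {
  stopifnot(n_reports >= 1, length(seed) == 1)
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(drug = character(),
                                      lambda = numeric())
  }
  if (any(drug_catalog$prob < 0 | drug_catalog$prob > 1)) {
    stop("configuration error: drug probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (anyDuplicated(drug_catalog$label)) {
    stop("configuration error: duplicate drug labels in catalog",
         call. = FALSE)
  }
  if (nrow(planted_effects) > 0) {
    if (!all(planted_effects$drug %in% drug_catalog$label)) {
      stop("configuration error: planted drug not in catalog",
           call. = FALSE)
    }
    if (any(!is.finite(planted_effects$lambda) |
            planted_effects$lambda < 1)) {
      stop("configuration error: lambda must be finite and >= 1",
           call. = FALSE)
    }
    if (any(background_event_rate * planted_effects$lambda > 1)) {
      stop("configuration error: background_event_rate * lambda ",
           "exceeds 1", call. = FALSE)
    }
  }
  if (background_event_rate < 0 || background_event_rate > 1) {
    stop("configuration error: background_event_rate must lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
         target_pt = target_pt,
         background_event_rate = background_event_rate,
         planted_effects = planted_effects, demographics = demographics,
         window = as.Date(window), seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Exposure and event draws plus the tallied ground-truth cells. Called
# first by every generator entry point so the truth is a fixed function of
# (config, seed) regardless of whether demographics are materialized.
synth_core <- function(config) {
  set.seed(config$seed)
  n <- config$n_reports
  cat <- config$drug_catalog
  J <- nrow(cat)
  lambda <- rep(1, J)
  if (nrow(config$planted_effects) > 0) {
    lambda[match(config$planted_effects$drug, cat$label)] <-
      config$planted_effects$lambda
  }
  exposed <- vector("list", J)
  lam_vec <- rep(1, n)
  for (j in seq_len(J)) {
    idx <- which(stats::runif(n) < cat$prob[j])
    exposed[[j]] <- idx
    if (lambda[j] > 1) {
      lam_vec[idx] <- pmax(lam_vec[idx], lambda[j])
    }
  }
  p_event <- pmin(1, config$background_event_rate * lam_vec)
  event <- stats::runif(n) < p_event
  n_event <- sum(event)

  bg <- config$background_event_rate
  p_exposed <- pmin(1, bg * lambda)
  ab <- lengths(exposed)
  a <- vapply(exposed, function(idx) sum(event[idx]), integer(1))
  truth <- tibble::tibble(
    drug = cat$label, lambda = lambda,
    # implied odds ratio of the planted effect (exact when planted drugs
    # do not overlap in reports; the event is binary per report)
    true_or = (p_exposed / (1 - p_exposed)) / (bg / (1 - bg)),
    a = a, b = as.integer(ab - a), c = as.integer(n_event - a),
    d = as.integer(n - ab - (n_event - a)), N = n
  )
  list(exposed = exposed, event = event, truth = truth, n_event = n_event)
}

#' Ground truth only (no report materialization)
#'
#' Draws exposures and events for a configuration and returns the tallied
#' per-drug 2x2 cells with each drug's planted relative risk and implied
#' odds ratio. Identical to the `truth` component of [synth_generate()]
#' for the same configuration; useful for fast Monte-Carlo studies.
#'
#' @param config A [synth_config()] object.
#' @return Tibble `drug`, `lambda`, `true_or`, `a`, `b`, `c`, `d`, `N`.
#' @export
synth_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  synth_core(config)$truth
}

# deterministic cosmetic noise on raw drug strings so the normalizer is
# exercised: every 3rd mention gains a dose token, every 7th a trailing
# period; both are stripped by cleaning.
decorate_drug_name <- function(label, k) {
  nm <- toupper(label)
  nm <- ifelse(k %% 3 == 0, paste(nm, "100MG"), nm)
  ifelse(k %% 7 == 0, paste0(nm, "."), nm)
}

#' Generate a synthetic FAERS-format report set with known ground truth
#'
#' Per report, drugs are mentioned independently with their catalog
#' probabilities; the target-event indicator is drawn with probability
#' `background_event_rate * max(lambda)` over mentioned drugs; sex, age,
#' weight, country, reporter occupation, outcomes and dates are drawn
#' independently from the demographics model. The first mentioned drug of
#' a report is coded primary suspect (PS), the rest secondary suspect
#' (SS). Every report carries one background reaction PT; event reports
#' additionally carry the target PT. Output uses the modern
#' (primaryid-keyed) FAERS dialect. With a fixed configuration the output
#' is byte-identical across runs.
#'
#' @param config A [synth_config()] object.
#' @param dir If non-`NULL`, write `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `THER.txt` (dollar-delimited) and `truth.tsv` there.
#' @return Invisibly, a list of class `synth_faers`: `tables` (the five
#'   dialect tibbles), `truth` (see [synth_truth()]), `event_ids`,
#'   `n_after_dedup`, `config`, and `paths` when files were written.
#' @export
synth_generate <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  core <- synth_core(config)
  n <- config$n_reports
  dem <- config$demographics

  caseid <- as.character(seq_len(n) + 10000L)
  primaryid <- paste0(caseid, "1")  # caseid * 10 + version

  sex <- sample(names(dem$sex), n, replace = TRUE, prob = dem$sex)
  sex_code <- dplyr::case_match(sex, "female" ~ "F", "male" ~ "M",
                                .default = "")

  strata <- names(dem$age_strata)
  p_known_age <- sum(dem$age_strata)
  has_age <- stats::runif(n) < p_known_age
  stratum <- sample(strata, n, replace = TRUE, prob = dem$age_strata)
  bounds <- do.call(rbind, strsplit(stratum, "-"))
  age_years <- stats::runif(n, as.numeric(bounds[, 1]),
                            as.numeric(bounds[, 2]))
  age <- ifelse(has_age, as.character(round(age_years)), "")
  age_cod <- ifelse(has_age, "YR", "")
  # a slice of known ages is coded in months to exercise unit conversion
  in_months <- has_age & (seq_len(n) %% 20L == 0L)
  age[in_months] <- as.character(round(age_years[in_months] * 12))
  age_cod[in_months] <- "MON"

  has_wt <- stats::runif(n) < dem$weight_known
  wt <- ifelse(has_wt,
               as.character(round(stats::rlnorm(n, dem$weight_meanlog,
                                                dem$weight_sdlog), 1)),
               "")
  country <- sample(names(dem$country), n, replace = TRUE,
                    prob = dem$country)
  occp <- sample(names(dem$occupation), n, replace = TRUE,
                 prob = dem$occupation)

  days <- as.integer(config$window[2] - config$window[1])
  fda_date <- config$window[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
  has_event_dt <- stats::runif(n) < dem$event_date_known
  event_date <- fda_date - sample.int(60L, n, replace = TRUE)
  tto <- round(stats::rlnorm(n, dem$tto_meanlog, dem$tto_sdlog))
  start_date <- event_date - tto

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    event_dt = ifelse(has_event_dt, format_faers_date(event_date), ""),
    fda_dt = format_faers_date(fda_date),
    age = age, age_cod = age_cod, sex = sex_code,
    wt = wt, wt_cod = ifelse(has_wt, "KG", ""),
    occp_cod = occp, occr_country = country
  )

  # drug mentions from the exposure draws
  mention <- data.table::rbindlist(lapply(seq_along(core$exposed),
    function(j) {
      idx <- core$exposed[[j]]
      if (length(idx) == 0) return(NULL)
      data.table::data.table(report = idx, drug_idx = j)
    }))
  drug <- if (nrow(mention) > 0) {
    data.table::setorder(mention, report, drug_idx)
    mention[, `:=`(drug_seq = seq_len(.N)), by = "report"]
    k <- seq_len(nrow(mention))
    tibble::tibble(
      primaryid = primaryid[mention$report],
      caseid = caseid[mention$report],
      drug_seq = as.character(mention$drug_seq),
      role_cod = ifelse(mention$drug_seq == 1L, "PS", "SS"),
      drugname = decorate_drug_name(
        config$drug_catalog$label[mention$drug_idx], k)
    )
  } else {
    tibble::tibble(primaryid = character(), caseid = character(),
                   drug_seq = character(), role_cod = character(),
                   drugname = character())
  }

  background_pts <- c("Nausea", "Headache", "Rash", "Fatigue",
                      "Diarrhoea", "Dizziness", "Pyrexia")
  bg_pt <- sample(background_pts, n, replace = TRUE)
  ev <- which(core$event)
  reac <- tibble::tibble(
    primaryid = c(primaryid, primaryid[ev]),
    caseid = c(caseid, caseid[ev]),
    pt = c(bg_pt, rep(config$target_pt, length(ev)))
  )

  n_out <- 1L + stats::rbinom(n, 2L, 0.2)
  outc_rows <- lapply(seq_len(n), function(i) {
    sample(names(dem$outcome), n_out[i], replace = FALSE,
           prob = dem$outcome)
  })
  outc <- tibble::tibble(
    primaryid = rep(primaryid, n_out),
    caseid = rep(caseid, n_out),
    outc_cod = unlist(outc_rows, use.names = FALSE)
  )

  # therapy start for the primary-suspect mention of each report
  first_mention <- drug[drug$role_cod == "PS", c("primaryid", "caseid",
                                                 "drug_seq")]
  rep_idx <- match(first_mention$primaryid, primaryid)
  ther <- tibble::tibble(
    primaryid = first_mention$primaryid,
    caseid = first_mention$caseid,
    dsg_drug_seq = first_mention$drug_seq,
    start_dt = format_faers_date(start_date[rep_idx])
  )

  out <- structure(
    list(
      tables = list(demo = demo, drug = drug, reac = reac, outc = outc,
                    ther = ther),
      truth = core$truth,
      event_ids = primaryid[ev],
      n_after_dedup = n,
      config = config
    ),
    class = "synth_faers"
  )
  if (!is.null(dir)) out$paths <- synth_write(out, dir)
  invisible(out)
}

#' Write a synthetic report set to FAERS-format files
#'
#' @param gen A `synth_faers` object from [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths (`demo`, `drug`, `reac`, `outc`,
#'   `ther`, `truth`), suitable for [read_faers_quarter()].
#' @export
synth_write <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             outc = file.path(dir, "OUTC.txt"),
             ther = file.path(dir, "THER.txt"))
  for (nm in names(paths)) {
    data.table::fwrite(gen$tables[[nm]], paths[[nm]], sep = "$",
                       quote = FALSE)
  }
  truth_path <- file.path(dir, "truth.tsv")
  data.table::fwrite(gen$truth, truth_path, sep = "\t", quote = FALSE)
  c(paths, truth = truth_path)
}

#' Inject duplicate case versions into a synthetic report set
#'
#' Re-emits a deterministic sample of `round(rate * n)` cases as a second
#' case version: same case key and content, incremented version, new
#' (larger) primaryid, duplicated rows in every table. Exercises
#' [deduplicate_reports()]; the expected post-deduplication report count
#' (`n_after_dedup`) is unchanged.
#'
#' @param gen A `synth_faers` object.
#' @param rate Fraction of cases to duplicate, in `[0, 1)`.
#' @param seed RNG seed for the case sample (default derived from the
#'   generator seed).
#' @return The modified `synth_faers` object.
#' @export
inject_duplicates <- function(gen, rate, seed = NULL) {
  stopifnot(inherits(gen, "synth_faers"), rate >= 0, rate < 1)
  n_dup <- round(rate * gen$n_after_dedup)
  if (n_dup == 0) return(gen)
  set.seed(seed %||% (gen$config$seed + 1000L))
  pick <- sample(gen$tables$demo$caseid, n_dup)
  for (nm in names(gen$tables)) {
    tab <- gen$tables[[nm]]
    dup <- tab[tab$caseid %in% pick, , drop = FALSE]
    dup$primaryid <- paste0(dup$caseid, "2")
    if (nm == "demo") dup$caseversion <- "2"
    gen$tables[[nm]] <- dplyr::bind_rows(tab, dup)
  }
  # event ids of duplicated cases exist under both primaryids; only the
  # surviving version's id matters downstream
  ev_case <- sub("1$", "", gen$event_ids)
  extra <- paste0(intersect(ev_case, pick), "2")
  gen$event_ids <- c(gen$event_ids, extra)
  gen
}
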