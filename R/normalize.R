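# Tokens stripped before dictionary lookup: dose units, formulation and
# route words, common salt/ester counter-ions. Deliberately conservative --
# nothing here is itself an active-ingredient name.
drug_stopwords <- c(
  "mg", "mcg", "ug", "g", "gm", "kg", "ml", "l", "iu", "meq", "units",
  "unit", "tablet", "tablets", "tab", "tabs", "capsule", "capsules",
  "cap", "caps", "caplet", "caplets", "pill", "pills", "injection",
  "injectable", "inj", "solution", "soln", "suspension", "syrup",
  "elixir", "cream", "ointment", "gel", "lotion", "patch", "patches",
  "spray", "drops", "suppository", "film", "coated", "chewable",
  "oral", "topical", "ophthalmic", "nasal", "intravenous", "iv", "im",
  "subcutaneous", "sc", "extended", "delayed", "immediate", "release",
  "er", "xr", "sr", "cr", "xl", "la", "od", "dr", "ec",
  "hcl", "hydrochloride", "sodium", "calcium", "potassium", "magnesium",
  "disodium", "sulfate", "sulphate", "bisulfate", "tartrate",
  "bitartrate", "citrate", "maleate", "mesylate", "besylate", "tosylate",
  "succinate", "fumarate", "acetate", "phosphate", "diphosphate",
  "nitrate", "bromide", "chloride", "iodide", "lactate", "gluconate",
  "carbonate", "valerate", "propionate", "dipropionate", "palmitate",
  "stearate", "benzoate", "salicylate", "pamoate", "hydrobromide",
  "dihydrate", "monohydrate", "trihydrate", "anhydrous", "hemihydrate"
)

#' Canonicalize a free-text drug string for dictionary lookup
#'
#' Lower-cases, replaces punctuation (except the `/` that joins
#' combination products) with spaces, drops numeric dose tokens
#' (`"20"`, `"20mg"`, `"0.5ml"`, ...) and salt/formulation stopwords, and
#' collapses whitespace.
#'
#' @param x Character vector of raw drug strings.
#' @return Character vector of cleaned strings.
#' @export
clean_drug_string <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9/ ]", " ", x)
  x <- gsub("\\s*/\\s*", "/", x)   # tighten combination separators
  tok <- strsplit(x, "\\s+")
  vapply(tok, function(tk) {
    tk <- tk[nzchar(tk)]
    drop <- tk %in% drug_stopwords |
      grepl("^[0-9][0-9.]*(mg|mcg|ug|g|ml|l|iu|%)?$", tk)
    paste(tk[!drop], collapse = " ")
  }, character(1))
}

#' Load a drug-normalization dictionary
#'
#' The dictionary is a UTF-8 tab-separated file of
#' `pattern<TAB>canonical` rows; lines starting with `#` are comments.
#' Patterns are cleaned with [clean_drug_string()] at load time, so a
#' pattern matches any raw string that cleans to the same form. Two
#' patterns that clean to the same string must map to the same canonical
#' label.
#'
#' @param path Path to the dictionary file. The default is the dictionary
#'   shipped with the package, seeded with drugs reported for
#'   autoimmune-like hepatitis plus common brand and salt synonyms.
#' @return A tibble of class `drug_dictionary` with columns `pattern`
#'   (cleaned) and `canonical`.
#' @export
read_drug_dictionary <- function(path = default_dictionary_path()) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", quote = "",
                           col.names = c("pattern", "canonical"),
                           colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  dict <- tibble::tibble(
    pattern = clean_drug_string(raw$pattern),
    canonical = trimws(raw$canonical)
  )
  dict <- dplyr::distinct(dict)
  dup <- duplicated(dict$pattern)
  if (any(dup)) {
    stop("dictionary patterns not unique after cleaning: ",
         paste(unique(dict$pattern[dup]), collapse = ", "), call. = FALSE)
  }
  class(dict) <- c("drug_dictionary", class(dict))
  dict
}

#' @rdname read_drug_dictionary
#' @export
default_dictionary_path <- function() {
  system.file("extdata", "drug_dictionary.tsv", package = "pvsignal",
              mustWork = TRUE)
}

#' Build a dictionary from a plain catalog of canonical labels
#'
#' Convenience constructor used with the synthetic generator: every label
#' becomes its own pattern.
#'
#' @param labels Character vector of canonical drug labels.
#' @return A `drug_dictionary` tibble.
#' @export
dictionary_from_labels <- function(labels) {
  dict <- tibble::tibble(pattern = clean_drug_string(labels),
                         canonical = labels)
  dict <- dplyr::distinct(dict)
  class(dict) <- c("drug_dictionary", class(dict))
  dict
}

#' Map raw drug strings to canonical labels
#'
#' Exact lookup of the cleaned string in the dictionary. Unresolved
#' strings return `NA` so they can be counted and inspected -- they are
#' never silently dropped.
#'
#' @param raw_name Character vector of free-text drug strings.
#' @param dict A `drug_dictionary` (see [read_drug_dictionary()]).
#' @return Character vector of canonical labels, `NA` where unresolved.
#' @examples
#' dict <- dictionary_from_labels(c("atorvastatin", "nitrofurantoin"))
#' normalize_drug(c("ATORVASTATIN CALCIUM 20MG", "Nitrofurantoin.",
#'                  "XYZZY-UNKNOWN"), dict)
#' @export
normalize_drug <- function(raw_name, dict) {
  if (!inherits(dict, "drug_dictionary") || nrow(dict) == 0) {
    stop("configuration error: empty or invalid drug dictionary",
         call. = FALSE)
  }
  dict$canonical[match(clean_drug_string(raw_name), dict$pattern)]
}

#' Normalize the drug mentions of a parsed quarter
#'
#' Adds a `normalized_name` column to a drug-mention tibble.
#'
#' @param drugs Tibble with a `raw_name` column.
#' @inheritParams normalize_drug
#' @return `drugs` with `normalized_name` appended.
#' @export
normalize_mentions <- function(drugs, dict) {
  drugs$normalized_name <- normalize_drug(drugs$raw_name, dict)
  drugs
}

#' Dictionary coverage of a set of drug mentions
#'
#' @param drugs Tibble with a `raw_name` column (as from
#'   [read_faers_quarter()]).
#' @inheritParams normalize_drug
#' @param top_n Number of unresolved strings to list.
#' @return List with `fraction_resolved` (in \[0, 1\]) and `unresolved`, a
#'   tibble of the most frequent unresolved raw strings (ties broken
#'   alphabetically).
#' @export
coverage_report <- function(drugs, dict, top_n = 20) {
  resolved <- !is.na(normalize_drug(drugs$raw_name, dict))
  frac <- if (nrow(drugs) == 0) NA_real_ else mean(resolved)
  unres <- drugs$raw_name[!resolved]
  tab <- tibble::tibble(raw_name = unres) |>
    dplyr::count(.data$raw_name, name = "n_mentions") |>
    dplyr::arrange(dplyr::desc(.data$n_mentions), .data$raw_name) |>
    utils::head(top_n)
  list(fraction_resolved = frac, unresolved = tab)
}
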