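test_that("modern quarter parses into the case model", {
  paths <- tiny_modern_quarter()
  dat <- suppressMessages(read_faers_quarter(paths))

  expect_equal(nrow(dat$reports), 7)  # 7 DEMO records incl. 2 versions
  expect_equal(nrow(dat$drugs), 9)
  r <- dat$reports

  # role codes pass through; invalid roles would be NA
  expect_setequal(unique(dat$drugs$role), c("PS", "SS", "C", "I"))

  # age unit conversion: 55 YR -> 55; 24 MON -> 2; implausible 999 -> NA
  expect_equal(r$age_years[r$primaryid == "1011"], 55)
  expect_equal(r$age_years[r$primaryid == "1021"], 2)
  expect_true(is.na(r$age_years[r$primaryid == "1041"]))

  # partial dates resolve to first day of the period; bad dates -> NA,
  # row retained
  expect_equal(r$event_date[r$primaryid == "1021"], as.Date("2019-12-01"))
  expect_equal(r$event_date[r$primaryid == "1041"], as.Date("2019-01-01"))
  expect_true(is.na(r$fda_receipt_date[r$primaryid == "1061"]))
  expect_true("1061" %in% r$primaryid)

  # pounds converted to kg
  expect_equal(r$weight_kg[r$primaryid == "1021"], 154 * 0.453592)

  # occupation and sex recoding
  expect_equal(r$reporter_occupation[r$primaryid == "1011"], "Physician")
  expect_equal(r$sex[r$primaryid == "1051"], "unknown")

  # outcome sets are deduplicated per report
  expect_setequal(r$outcomes[r$primaryid == "1011"][[1]],
                  c("hospitalization", "other serious"))
})

test_that("legacy ISR-keyed quarter is harmonized to the modern keys", {
  paths <- tiny_legacy_quarter()
  dat <- suppressMessages(read_faers_quarter(paths, layout = "legacy"))
  expect_equal(dat$reports$primaryid, c("501", "502"))
  expect_equal(dat$reports$caseid, c("51", "52"))
  expect_equal(dat$reports$case_version, c(0L, 0L))
  expect_equal(dat$reports$age_years, c(60, 50))  # 5 decades -> 50 years
  expect_equal(dat$drugs$role, c("PS", "PS"))
})

test_that("missing mandatory column raises a schema error naming it", {
  dir <- withr::local_tempdir()
  paths <- tiny_modern_quarter(dir)
  drug_lines <- readLines(paths$drug)
  # drop the role_cod column entirely
  writeLines(gsub("\\$(PS|SS|C|I)\\$", "$", sub("\\$role_cod\\$", "$",
                                                drug_lines)),
             paths$drug)
  expect_error(suppressMessages(read_faers_quarter(paths)),
               "role_cod")
})

test_that("empty files yield empty results with a warning", {
  dir <- withr::local_tempdir()
  paths <- tiny_modern_quarter(dir)
  file.create(paths$reac)  # truncate to zero bytes
  expect_warning(dat <- suppressMessages(read_faers_quarter(paths)),
                 "empty")
  expect_equal(nrow(dat$reactions), 0)
  expect_equal(nrow(dat$reports), 7)
})

test_that("deduplication keeps the highest version/date/id and is idempotent", {
  paths <- tiny_modern_quarter()
  dat <- suppressMessages(read_faers_quarter(paths))
  dd <- suppressMessages(deduplicate_reports(dat$reports))

  # one row per caseid; case 103 keeps version 2
  expect_equal(anyDuplicated(dd$caseid), 0)
  expect_true("1032" %in% dd$primaryid)
  expect_false("1031" %in% dd$primaryid)
  expect_equal(nrow(dd), 6)

  # distinct caseids all kept; idempotence
  expect_identical(suppressMessages(deduplicate_reports(dd)), dd)

  # exact duplicate rows collapse to one
  dup <- rbind(dat$reports, dat$reports[1, ])
  expect_equal(sum(suppressMessages(
    deduplicate_reports(dup))$primaryid == "1011"), 1)

  # ties on version broken by receipt date
  two <- dat$reports[dat$reports$caseid == "103", ]
  two$case_version <- c(1L, 1L)
  kept <- suppressMessages(deduplicate_reports(two))
  expect_equal(kept$primaryid, "1032")  # later fda date wins
})

test_that("event retrieval matches case-insensitively with collapsed whitespace", {
  paths <- tiny_modern_quarter()
  dat <- suppressMessages(read_faers_quarter(paths))
  ids <- filter_event(dat$reactions, "autoimmune hepatitis")
  expect_setequal(ids, c("1011", "1021", "1041"))
  expect_equal(filter_event(tibble::tibble(primaryid = character(),
                                           pt = character()),
                            "autoimmune hepatitis"),
               character())
})

test_that("window filtering changes membership only, never field values", {
  paths <- tiny_modern_quarter()
  dat <- suppressMessages(read_faers_quarter(paths))
  w <- filter_window(dat$reports, "2020-03-01", "2020-03-31")
  expect_setequal(w$primaryid, c("1011", "1021", "1031"))
  expect_identical(w, dat$reports[dat$reports$primaryid %in% w$primaryid, ])
})

test_that("write/read round trip preserves parsed field values", {
  paths <- tiny_modern_quarter()
  dat <- suppressMessages(read_faers_quarter(paths))
  dir2 <- withr::local_tempdir()
  files <- write_faers_quarter(dat, dir2)
  dat2 <- suppressMessages(read_faers_quarter(as.list(files)))
  for (part in c("reports", "drugs", "reactions", "therapy")) {
    expect_equal(dat2[[part]], dat[[part]], ignore_attr = TRUE)
  }
  expect_equal(dplyr::arrange(dat2$outcomes, primaryid, outcome),
               dplyr::arrange(dat$outcomes, primaryid, outcome))
})
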