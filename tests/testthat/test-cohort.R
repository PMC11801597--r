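test_that("percentages use half-up rounding at two decimals", {
  expect_equal(percent_of(1490, 5723), 26.04)
  expect_equal(percent_of(2573, 8018), 32.09)
  expect_equal(percent_of(0, 5723), 0)
  expect_error(percent_of(1, 0), "denominator")
  expect_error(percent_of(5, 4))
  # complement property
  withr::with_seed(2, {
    n <- sample(100:10000, 50)
    a <- vapply(n, function(k) sample.int(k, 1), integer(1))
    expect_true(all(abs(percent_of(a, n) + percent_of(n - a, n) - 100)
                    <= 0.01))
  })
  # the case where banker's rounding would disagree
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})

mk_cohort_reports <- function(ages, sex = "female",
                              country = "United States",
                              occ = "Physician",
                              fda = as.Date("2020-06-01")) {
  n <- length(ages)
  tibble::tibble(
    primaryid = as.character(seq_len(n)), caseid = as.character(seq_len(n)),
    case_version = 1L, fda_receipt_date = rep(fda, n),
    event_date = rep(as.Date(NA), n), sex = rep(sex, n),
    age_value = ages, age_unit = "YR", age_years = ages,
    weight_kg = NA_real_, reporter_occupation = rep(occ, n),
    reporter_country = rep(country, n),
    outcomes = rep(list(character()), n)
  )
}

test_that("age binning is left-closed, exhaustive and handles missing", {
  co <- summarize_cohort(mk_cohort_reports(c(10, 30, 50, 70, 80)))
  expect_equal(co$age$count, c(1L, 1L, 1L, 1L, 1L, 0L))
  expect_equal(co$age$level,
               c("<19", "19~45", "45~65", "65~75", ">=75", "unknown"))
  # boundary value 45 falls in the upper bin
  co45 <- summarize_cohort(mk_cohort_reports(c(45, 19, 75)))
  expect_equal(co45$age$count[co45$age$level == "45~65"], 1L)
  expect_equal(co45$age$count[co45$age$level == "19~45"], 1L)
  expect_equal(co45$age$count[co45$age$level == ">=75"], 1L)
  # all missing -> unknown = N, medians missing
  com <- summarize_cohort(mk_cohort_reports(rep(NA_real_, 4)))
  expect_equal(com$age$count[com$age$level == "unknown"], 4L)
  expect_true(is.na(com$age_summary$median))
  # bins + unknown partition N
  expect_equal(sum(co$age$count), co$n)
})

test_that("medians and quartiles use type-7 interpolation on known values", {
  co <- summarize_cohort(mk_cohort_reports(c(42, 55, 67)))
  expect_equal(co$age_summary$median, 55)
  expect_equal(co$age_summary$q1, 48.5)   # (n-1)p + 1 = 1.5
  expect_equal(co$age_summary$q3, 61)
  expect_equal(co$age_summary$n, 3L)
})

test_that("single-valued variables sum to N and 100 percent; outcomes use entry denominator", {
  r <- mk_cohort_reports(c(30, 40, 50, 60))
  r$sex <- c("female", "female", "male", "unknown")
  r$outcomes <- list(c("hospitalization", "death"), "other serious",
                     "other serious", character())
  co <- summarize_cohort(r)
  expect_equal(sum(co$sex$count), 4L)
  expect_equal(sum(co$sex$percent), 100, tolerance = 0.1)
  # 4 outcome entries in total
  expect_equal(sum(co$outcomes$count), 4L)
  expect_equal(co$outcomes$percent[co$outcomes$level == "hospitalization"],
               25)
  expect_equal(co$outcomes$percent[co$outcomes$level == "other serious"],
               50)
})

test_that("country grouping keeps the top reporters and pools the rest", {
  r <- mk_cohort_reports(rep(50, 8))
  r$reporter_country <- c("United States", "United States", "Germany",
                          "Japan", "France", "United Kingdom", "Italy",
                          "Spain")
  co <- summarize_cohort(r, top_countries = 5)
  expect_equal(co$country$count[co$country$level == "other"], 2L)
  expect_true("United States" %in% co$country$level)
})

test_that("yearly counts cover the window and sum to N", {
  r <- mk_cohort_reports(rep(40, 5))
  r$fda_receipt_date <- as.Date(c("2019-01-02", "2019-07-01",
                                  "2020-03-01", "2021-12-31",
                                  "2021-01-01"))
  co <- summarize_cohort(r)
  expect_equal(co$yearly_counts$year, c(2019L, 2020L, 2021L))
  expect_equal(co$yearly_counts$count, c(2L, 1L, 2L))
  expect_equal(sum(co$yearly_counts$count), co$n)
})

test_that("time to onset is event minus earliest suspect start, with implausibles missing", {
  reports <- tibble::tibble(
    primaryid = c("1", "2", "3", "4"),
    event_date = as.Date(c("2020-03-27", "2020-03-27", "2019-12-31",
                           "2020-03-27")))
  drugs <- tibble::tibble(
    primaryid = c("1", "1", "2", "3", "4"),
    drug_seq = c(1L, 2L, 1L, 1L, 1L),
    role = c("PS", "SS", "PS", "PS", "C"))
  therapy <- tibble::tibble(
    primaryid = c("1", "1", "3"),
    drug_seq = c(1L, 2L, 1L),
    start_date = as.Date(c("2020-01-01", "2020-02-01", "2020-01-01")))
  tto <- time_to_onset(reports, drugs, therapy)
  expect_equal(tto$tto_days[tto$primaryid == "1"], 86)  # earliest start
  expect_true(is.na(tto$tto_days[tto$primaryid == "2"]))  # no start date
  expect_true(is.na(tto$tto_days[tto$primaryid == "3"]))  # event < start
  expect_true(is.na(tto$tto_days[tto$primaryid == "4"]))  # no suspect role
})
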