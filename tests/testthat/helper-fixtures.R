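# In-code fixtures: a hand-built miniature FAERS quarter with known
# structure, written to a temp dir on demand.

write_lines_file <- function(lines, path) {
  writeLines(lines, path)
  path
}

# Six cases; case 103 has two versions (primaryids 1031/1032). Drug X
# (atorvastatin) in reports 1011, 1021, 1032; target event in 1011, 1021,
# 1041. After dedup: 6 reports.
new_fixture_dir <- function() {
  dir <- tempfile("pvsignal-fixture-")
  dir.create(dir)
  dir
}

tiny_modern_quarter <- function(dir = new_fixture_dir()) {
  demo <- c(
    "primaryid$caseid$caseversion$event_dt$fda_dt$age$age_cod$sex$wt$wt_cod$occp_cod$occr_country",
    "1011$101$1$20200101$20200301$55$YR$F$70$KG$MD$US",
    "1021$102$1$201912$20200315$24$MON$M$154$LBS$CN$DE",
    "1031$103$1$$20200320$45$YR$F$$$PH$JP",
    "1032$103$2$$20200401$46$YR$F$$$PH$JP",
    "1041$104$1$2019$20200410$999$YR$M$$$OT$FR",
    "1051$105$1$$20200415$$$U$$$LW$GB",
    "1061$106$1$$bad-date$70$YR$F$$$RN$US"
  )
  drug <- c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "1011$101$1$PS$ATORVASTATIN CALCIUM 20MG",
    "1011$101$2$C$Nitrofurantoin.",
    "1021$102$1$PS$Lipitor",
    "1021$102$2$SS$XYZZY-UNKNOWN",
    "1032$103$1$PS$atorvastatin",
    "1032$103$2$PS$ATORVASTATIN",
    "1041$104$1$PS$minocycline",
    "1051$105$1$SS$doxycycline",
    "1061$106$1$I$mesalamine"
  )
  reac <- c(
    "primaryid$caseid$pt",
    "1011$101$Autoimmune Hepatitis",
    "1011$101$Nausea",
    "1021$102$autoimmune  hepatitis",
    "1032$103$Rash",
    "1041$104$AUTOIMMUNE HEPATITIS",
    "1051$105$Headache",
    "1061$106$Fatigue"
  )
  outc <- c(
    "primaryid$caseid$outc_cod",
    "1011$101$HO",
    "1011$101$OT",
    "1021$102$DE",
    "1041$104$LT",
    "1051$105$OT"
  )
  ther <- c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "1011$101$1$20191007",
    "1021$102$1$20191201",
    "1041$104$1$20190101"
  )
  list(
    demo = write_lines_file(demo, file.path(dir, "DEMO.txt")),
    drug = write_lines_file(drug, file.path(dir, "DRUG.txt")),
    reac = write_lines_file(reac, file.path(dir, "REAC.txt")),
    outc = write_lines_file(outc, file.path(dir, "OUTC.txt")),
    ther = write_lines_file(ther, file.path(dir, "THER.txt"))
  )
}

tiny_legacy_quarter <- function(dir = new_fixture_dir()) {
  demo <- c(
    "isr$case$event_dt$fda_dt$age$age_cod$gndr_cod$wt$wt_cod$occp_cod$reporter_country",
    "501$51$20080101$20080301$60$YR$F$65$KG$MD$FRANCE",
    "502$52$$20080315$5$DEC$M$$$CN$JAPAN"
  )
  drug <- c(
    "isr$drug_seq$role_cod$drugname",
    "501$1$PS$HYDRALAZINE",
    "502$1$PS$MINOCYCLINE"
  )
  reac <- c(
    "isr$pt",
    "501$Autoimmune hepatitis",
    "502$Rash"
  )
  list(
    demo = write_lines_file(demo, file.path(dir, "DEMO.txt")),
    drug = write_lines_file(drug, file.path(dir, "DRUG.txt")),
    reac = write_lines_file(reac, file.path(dir, "REAC.txt"))
  )
}

# exhaustive set-intersection oracle for contingency cells
brute_force_cells <- function(report_ids, drug_sets, event_ids) {
  N <- length(report_ids)
  event_ids <- intersect(event_ids, report_ids)
  lapply(drug_sets, function(ids) {
    ids <- intersect(ids, report_ids)
    a <- length(intersect(ids, event_ids))
    b <- length(setdiff(ids, event_ids))
    c <- length(setdiff(event_ids, ids))
    list(a = a, b = b, c = c, d = N - a - b - c)
  })
}

# random strictly-positive 2x2 tables
random_tables <- function(n, max_cell = 200, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = sample.int(max_cell, n, replace = TRUE),
      b = sample.int(max_cell, n, replace = TRUE),
      c = sample.int(max_cell, n, replace = TRUE),
      d = sample.int(max_cell * 10, n, replace = TRUE)
    )
  })
}

# independent odds-ratio route: saturated logistic regression; exp(coef)
# equals the cross-product ratio but is computed by IRLS, not arithmetic
glm_odds_ratio <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  exposed <- c(1, 1, 0, 0)
  event <- c(1, 0, 1, 0)
  fit <- suppressWarnings(
    stats::glm(event ~ exposed, weights = counts, family = stats::binomial()))
  unname(exp(stats::coef(fit)["exposed"]))
}
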