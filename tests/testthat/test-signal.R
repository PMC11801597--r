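test_that("closed-form values on the worked 2x2 tables", {
  r <- ror_stats(10, 20, 30, 240)
  expect_equal(r$ror, 4.0)
  expect_equal(r$ror_lo, exp(log(4) - 1.96 * sqrt(0.1875)),
               tolerance = 1e-12)
  expect_equal(round(r$ror_lo, 3), 1.712)
  expect_equal(round(r$ror_hi, 3), 9.346)

  p <- prr_stats(10, 20, 30, 240)
  expect_equal(p$prr, 3.0)
  expect_equal(p$chisq, 300 * (abs(10 * 240 - 20 * 30) - 150)^2 /
                 (30 * 270 * 40 * 260), tolerance = 1e-12)
  expect_equal(round(p$chisq, 2), 9.70)

  bc <- bcpnn_stats(10, 20, 30, 240)
  expect_equal(bc$ic_raw, log2(2.5))
  expect_equal(round(bc$ic, 3), 1.086)

  e <- ebgm_stats(10, 20, 30, 240)
  expect_equal(e$ebgm, 2.5)
  expect_equal(round(e$ebgm05, 3), 1.070)
})

test_that("a symmetric table is null on all four statistics", {
  expect_equal(ror_stats(5, 5, 5, 5)$ror, 1.0)
  r <- ror_stats(5, 5, 5, 5)
  expect_true(r$ror_lo < 1 && r$ror_hi > 1)
  p <- prr_stats(5, 5, 5, 5)
  expect_equal(p$prr, 1.0)
  expect_equal(p$chisq, 0)  # Yates term floored at zero
  expect_equal(bcpnn_stats(5, 5, 5, 5)$ic, 0)  # exactly, default priors
  expect_equal(ebgm_stats(5, 5, 5, 5)$ebgm, 1.0)
})

test_that("exact independence gives ror = prr = ebgm = 1 and raw IC 0", {
  # margins chosen so ad = bc exactly
  tabs <- list(c(5, 95, 495, 9405), c(2, 18, 198, 1782),
               c(10, 90, 90, 810))
  for (t in tabs) {
    expect_equal(ror_stats(t[1], t[2], t[3], t[4])$ror, 1)
    expect_equal(prr_stats(t[1], t[2], t[3], t[4])$prr, 1)
    expect_equal(ebgm_stats(t[1], t[2], t[3], t[4])$ebgm, 1)
    expect_equal(bcpnn_stats(t[1], t[2], t[3], t[4])$ic_raw, 0)
  }
})

test_that("increasing a with b, c, d fixed strictly increases every statistic", {
  b <- 40; c <- 25; d <- 900
  a <- 1:30
  ror <- ror_stats(a, b, c, d)$ror
  prr <- prr_stats(a, b, c, d)$prr
  ic <- bcpnn_stats(a, b, c, d)$ic_raw
  ebgm <- ebgm_stats(a, b, c, d)$ebgm
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(ebgm) > 0))
})

test_that("BCPNN shrinkage pulls E[IC] towards zero and vanishes at scale", {
  tabs <- random_tables(200, seed = 11)
  bc <- bcpnn_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  # exact shrinkage for clear associations; near the null the posterior
  # mean's small-count bias (~log2(1 + 1/a) bits) can overshoot zero
  away <- abs(bc$ic_raw) >= 1
  expect_true(all(abs(bc$ic[away]) <= abs(bc$ic_raw[away]) + 1e-9))
  expect_true(all(abs(bc$ic) - abs(bc$ic_raw) <= log2(1 + 1 / tabs$a)))
  # proportional x10 / x100 scaling converges E[IC] to the raw IC
  one <- c(a = 6, b = 40, c = 25, d = 900)
  gap <- sapply(c(1, 10, 100), function(k) {
    s <- bcpnn_stats(one["a"] * k, one["b"] * k, one["c"] * k,
                     one["d"] * k)
    abs(s$ic - s$ic_raw)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("ror exceeds prr on positively associated tables and matches the glm oracle", {
  tabs <- random_tables(300, seed = 5)
  pos <- tabs[tabs$a * tabs$d > tabs$b * tabs$c, ]
  r <- ror_stats(pos$a, pos$b, pos$c, pos$d)$ror
  p <- prr_stats(pos$a, pos$b, pos$c, pos$d)$prr
  expect_true(all(r >= p & p >= 0))
  expect_true(all(r[r > 1] >= p[r > 1]))

  # independent IRLS route for a subsample
  idx <- seq(1, nrow(tabs), by = 6)
  for (i in idx) {
    expect_equal(ror_stats(tabs$a[i], tabs$b[i], tabs$c[i],
                           tabs$d[i])$ror,
                 glm_odds_ratio(tabs$a[i], tabs$b[i], tabs$c[i],
                                tabs$d[i]),
                 tolerance = 1e-6)
  }
})

test_that("Yates chi-square agrees with stats::chisq.test", {
  tabs <- random_tables(50, seed = 3)
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2,
                byrow = TRUE)
    expect_equal(prr_stats(tabs$a[i], tabs$b[i], tabs$c[i],
                           tabs$d[i])$chisq,
                 unname(suppressWarnings(
                   stats::chisq.test(m, correct = TRUE)$statistic)),
                 tolerance = 1e-9)
  }
})

test_that("zero cells error by name unless the continuity correction is enabled", {
  expect_error(ror_stats(0, 5, 5, 5), "'a'")
  expect_error(ror_stats(3, 0, 5, 5), "'b'")
  expect_error(ebgm_stats(3, 5, 0, 5), "'c'")
  corrected <- ror_stats(0, 5, 5, 5, zero_correction = TRUE)
  expect_equal(corrected$ror, (0.5 * 5.5) / (5.5 * 5.5))
  # BCPNN tolerates a zero a but not an empty margin
  expect_equal(nrow(bcpnn_stats(0, 5, 5, 5)), 1)
  expect_error(bcpnn_stats(0, 0, 5, 5), "undefined")
})

test_that("threshold classification applies each rule with strict inequalities", {
  base <- tibble::tibble(
    drug = "x", a = 10L, ror = 5, ror_lo = 2, ror_hi = 10,
    prr = 5, prr_lo = 2, prr_hi = 10, chisq = 30,
    ic = 1, ic025 = 0.5, ebgm = 5, ebgm05 = 3)
  out <- classify_signals(base)
  expect_true(out$consensus)

  # the minimum-case rule trumps a huge ror
  small <- dplyr::mutate(base, a = 2L, ror = 100, ror_lo = 50)
  expect_false(classify_signals(small)$ror_pos)

  # strict inequality at the IC025 boundary
  edge <- dplyr::mutate(base, ic025 = 0)
  expect_false(classify_signals(edge)$bcpnn_pos)
  expect_false(classify_signals(edge)$consensus)

  # alternative PRR rule: PRR > 2 and chi-square > 4
  alt <- pv_thresholds(prr_rule = "prr2_chi4")
  weak <- dplyr::mutate(base, prr = 1.5, prr_lo = 1.2)
  expect_false(classify_signals(weak, alt)$prr_pos)
  expect_true(classify_signals(base, alt)$prr_pos)
})

test_that("signal ranking orders by ror then case count then name", {
  s <- tibble::tibble(drug = c("b", "a", "c", "d"),
                      a = c(5L, 9L, 9L, 2L),
                      ror = c(3, 3, 3, 8))
  ranked <- rank_signals(s)
  expect_equal(ranked$drug, c("d", "a", "c", "b"))
  expect_equal(nrow(rank_signals(s, top_n = 2)), 2)
  # top-N is a prefix of the full ranking
  expect_equal(rank_signals(s, top_n = 2), utils::head(ranked, 2))
})
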