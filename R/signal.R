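# Disproportionality statistics for drug-event 2x2 tables.
#
# Cell layout (per drug, against the whole database):
#              target event   other events
#   drug            a              b
#   no drug         c              d
#
# All four statistics compare the observed co-reporting count a with its
# expectation under independence; they differ in the comparator and in
# whether Bayesian shrinkage is applied.

check_cells <- function(a, b, c, d, zero_correction) {
  cells <- cbind(a = a, b = b, c = c, d = d)
  if (any(cells < 0, na.rm = TRUE)) {
    stop("negative cell count in 2x2 table", call. = FALSE)
  }
  zero <- cells == 0
  if (any(zero) && !zero_correction) {
    bad <- colnames(cells)[which(apply(zero, 2, any))]
    stop("undefined result: cell '", bad[[1]],
         "' is zero (enable zero_correction for the Haldane-Anscombe ",
         "+0.5 adjustment)", call. = FALSE)
  }
  if (zero_correction) {
    # +0.5 to all four cells of any table containing a zero
    adj <- apply(zero, 1, any)
    cells[adj, ] <- cells[adj, , drop = FALSE] + 0.5
  }
  cells
}

# 95% log-normal interval with the conventional 1.96 multiplier (as the
# screening formulas are printed, rather than qnorm(0.975))
wald_ci <- function(est, se_log, z = 1.96) {
  list(lo = exp(log(est) - z * se_log), hi = exp(log(est) + z * se_log))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a/c) / (b/d)` with the log-normal Wald interval,
#' `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @param zero_correction If `TRUE`, tables containing a zero cell get
#'   0.5 added to all four cells (Haldane-Anscombe); if `FALSE` (default)
#'   a zero cell is an error naming the cell.
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`.
#' @examples
#' ror_stats(10, 20, 30, 240)  # ROR 4.0, CI (1.71, 9.35)
#' @export
ror_stats <- function(a, b, c, d, zero_correction = FALSE) {
  k <- check_cells(a, b, c, d, zero_correction)
  est <- (k[, "a"] * k[, "d"]) / (k[, "b"] * k[, "c"])
  se <- sqrt(1 / k[, "a"] + 1 / k[, "b"] + 1 / k[, "c"] + 1 / k[, "d"])
  ci <- wald_ci(est, se)
  tibble::tibble(ror = unname(est), ror_lo = unname(ci$lo),
                 ror_hi = unname(ci$hi))
}

#' Proportional reporting ratio, interval and Yates chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with
#' `SE(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. The chi-square is
#' the Yates continuity-corrected 2x2 statistic, floored at zero.
#'
#' @inheritParams ror_stats
#' @return Tibble with columns `prr`, `prr_lo`, `prr_hi`, `chisq`.
#' @examples
#' prr_stats(10, 20, 30, 240)  # PRR 3.0, chi-square 9.70
#' @export
prr_stats <- function(a, b, c, d, zero_correction = FALSE) {
  k <- check_cells(a, b, c, d, zero_correction)
  ka <- k[, "a"]; kb <- k[, "b"]; kc <- k[, "c"]; kd <- k[, "d"]
  est <- (ka / (ka + kb)) / (kc / (kc + kd))
  se <- sqrt(1 / ka - 1 / (ka + kb) + 1 / kc - 1 / (kc + kd))
  ci <- wald_ci(est, se)
  # chi-square on the raw (uncorrected) counts
  A <- a + 0; B <- b + 0; C <- c + 0; D <- d + 0
  N <- A + B + C + D
  num <- pmax(0, abs(A * D - B * C) - N / 2)
  chisq <- N * num^2 / ((A + B) * (C + D) * (A + C) * (B + D))
  tibble::tibble(prr = unname(est), prr_lo = unname(ci$lo),
                 prr_hi = unname(ci$hi), chisq = unname(chisq))
}

#' BCPNN information component with Bayesian shrinkage
#'
#' The information component is `IC = log2` of the observed-over-expected
#' co-reporting probability. The Bayesian confidence propagation neural
#' network places Dirichlet-type priors on the cell probabilities; the
#' closed-form posterior expectation `E[IC]` and variance `V[IC]` shrink
#' the raw IC towards zero for sparse cells, and the signal bound is
#' `IC025 = E[IC] - 2 sqrt(V[IC])`.
#'
#' The default hyperparameters (`gamma11 = alpha1 = beta1 = 1`,
#' `alpha = beta = 2`) give `E[IC] = 0` exactly for a perfectly symmetric
#' table.
#'
#' @inheritParams ror_stats
#' @param gamma11,alpha1,beta1,alpha,beta BCPNN prior hyperparameters.
#' @return Tibble with columns `ic_raw`, `ic` (`= E[IC]`), `v_ic`,
#'   `ic025`.
#' @examples
#' bcpnn_stats(5, 5, 5, 5)       # E[IC] exactly 0
#' bcpnn_stats(10, 20, 30, 240)  # raw IC log2(2.5), E[IC] ~ 1.086
#' @export
bcpnn_stats <- function(a, b, c, d, gamma11 = 1, alpha1 = 1, beta1 = 1,
                        alpha = 2, beta = 2) {
  a <- a + 0; b <- b + 0; c <- c + 0; d <- d + 0
  N <- a + b + c + d
  if (any(N <= 0) || any(a + b == 0) || any(a + c == 0)) {
    stop("undefined result: BCPNN requires N > 0, a+b > 0 and a+c > 0",
         call. = FALSE)
  }
  ic_raw <- log2(a * N / ((a + b) * (a + c)))
  gamma <- gamma11 * (N + alpha) * (N + beta) /
    ((a + b + alpha1) * (a + c + beta1))
  e_ic <- log2((a + gamma11) * (N + alpha) * (N + beta) /
                 ((N + gamma) * (a + b + alpha1) * (a + c + beta1)))
  v_ic <- (1 / log(2)^2) * (
    (N - a + gamma - gamma11) / ((a + gamma11) * (1 + N + gamma)) +
    (N - (a + b) + alpha - alpha1) / ((a + b + alpha1) * (1 + N + alpha)) +
    (N - (a + c) + beta - beta1) / ((a + c + beta1) * (1 + N + beta))
  )
  tibble::tibble(ic_raw = ic_raw, ic = e_ic, v_ic = v_ic,
                 ic025 = e_ic - 2 * sqrt(v_ic))
}

#' Empirical Bayes geometric mean (relative reporting ratio form)
#'
#' `EBGM = a N / ((a+b)(a+c))`, the observed-over-expected relative
#' reporting ratio, with a log-normal interval using
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. This is the closed-form screening
#' variant; no gamma-mixture (MGPS) posterior is fitted.
#'
#' @inheritParams ror_stats
#' @return Tibble with columns `ebgm`, `ebgm05`, `ebgm95`.
#' @examples
#' ebgm_stats(10, 20, 30, 240)  # EBGM 2.5, EBGM05 ~ 1.07
#' @export
ebgm_stats <- function(a, b, c, d, zero_correction = FALSE) {
  k <- check_cells(a, b, c, d, zero_correction)
  ka <- k[, "a"]; kb <- k[, "b"]; kc <- k[, "c"]; kd <- k[, "d"]
  N <- ka + kb + kc + kd
  est <- ka * N / ((ka + kb) * (ka + kc))
  se <- sqrt(1 / ka + 1 / kb + 1 / kc + 1 / kd)
  ci <- wald_ci(est, se)
  tibble::tibble(ebgm = unname(est), ebgm05 = unname(ci$lo),
                 ebgm95 = unname(ci$hi))
}

#' Signal-detection thresholds
#'
#' Bundles the conventional decision rules: ROR and PRR are positive when
#' the lower 95% bound exceeds 1 with at least `min_cases` reports (the
#' alternative `prr2_chi4` rule asks PRR > 2 and chi-square > 4 instead of
#' the CI); BCPNN is positive when `IC025 > 0`; EBGM when `EBGM05 > 2`.
#' All inequalities are strict.
#'
#' @param min_cases Minimum `a` for the frequentist flags (default 3).
#' @param prr_rule `"ci_gt_1"` (default) or `"prr2_chi4"`.
#' @param ror_ci_gt,ic025_gt,ebgm05_gt Numeric cut points.
#' @return A list of class `pv_thresholds`.
#' @export
pv_thresholds <- function(min_cases = 3,
                          prr_rule = c("ci_gt_1", "prr2_chi4"),
                          ror_ci_gt = 1, ic025_gt = 0, ebgm05_gt = 2) {
  structure(
    list(min_cases = min_cases, prr_rule = match.arg(prr_rule),
         ror_ci_gt = ror_ci_gt, ic025_gt = ic025_gt,
         ebgm05_gt = ebgm05_gt),
    class = "pv_thresholds"
  )
}

#' Compute all four disproportionality statistics for contingency tables
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (and usually
#'   `drug`), as from [build_contingency()].
#' @inheritParams ror_stats
#' @inheritParams bcpnn_stats
#' @return The input columns `drug` (if present) and `a`, followed by
#'   `ror`, `ror_lo`, `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chisq`, `ic`,
#'   `ic025`, `ebgm`, `ebgm05` (plus `ic_raw`, `v_ic`, `ebgm95`).
#' @export
signal_stats <- function(tables, zero_correction = FALSE,
                         gamma11 = 1, alpha1 = 1, beta1 = 1,
                         alpha = 2, beta = 2) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  out <- dplyr::bind_cols(
    ror_stats(a, b, c, d, zero_correction),
    prr_stats(a, b, c, d, zero_correction),
    bcpnn_stats(a, b, c, d, gamma11, alpha1, beta1, alpha, beta),
    ebgm_stats(a, b, c, d, zero_correction)
  )
  id_cols <- intersect(c("drug", "a"), names(tables))
  dplyr::bind_cols(tables[id_cols], out)
}

#' Apply signal thresholds and form the consensus flag
#'
#' Works on computed statistics or on any tibble carrying the needed
#' columns (`a`, `ror_lo`, `prr_lo` or `prr`+`chisq`, `ic025`, `ebgm05`),
#' e.g. a published signal table, so printed results can be re-classified.
#'
#' @param stats Tibble of statistics (see [signal_stats()]).
#' @param thresholds A [pv_thresholds()] object.
#' @return `stats` with logical columns `ror_pos`, `prr_pos`,
#'   `bcpnn_pos`, `ebgm_pos` and `consensus` (all four positive).
#' @export
classify_signals <- function(stats, thresholds = pv_thresholds()) {
  stopifnot(inherits(thresholds, "pv_thresholds"))
  th <- thresholds
  min_ok <- stats$a >= th$min_cases
  stats$ror_pos <- min_ok & stats$ror_lo > th$ror_ci_gt
  stats$prr_pos <- if (th$prr_rule == "ci_gt_1") {
    min_ok & stats$prr_lo > 1
  } else {
    min_ok & stats$prr > 2 & stats$chisq > 4
  }
  stats$bcpnn_pos <- stats$ic025 > th$ic025_gt
  stats$ebgm_pos <- stats$ebgm05 > th$ebgm05_gt
  stats$consensus <- stats$ror_pos & stats$prr_pos & stats$bcpnn_pos &
    stats$ebgm_pos
  stats
}

#' Rank a signal table
#'
#' Default ordering is by ROR descending (ties broken by case count
#' descending, then alphabetically by drug), the conventional
#' signal-strength ranking; `by = "cases"` ranks by reporting frequency.
#'
#' @param stats Signal tibble with `drug`, `a` and `ror` columns.
#' @param top_n Keep the first `top_n` rows (`Inf` keeps all).
#' @param by `"ror"` or `"cases"`.
#' @return The ranked (and truncated) tibble.
#' @export
rank_signals <- function(stats, top_n = Inf, by = c("ror", "cases")) {
  by <- match.arg(by)
  ranked <- if (by == "ror") {
    dplyr::arrange(stats, dplyr::desc(.data$ror), dplyr::desc(.data$a),
                   .data$drug)
  } else {
    dplyr::arrange(stats, dplyr::desc(.data$a), dplyr::desc(.data$ror),
                   .data$drug)
  }
  utils::head(ranked, top_n)
}
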