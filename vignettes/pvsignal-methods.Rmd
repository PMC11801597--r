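---
title: "Disproportionality signal detection with pvsignal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect case reports of suspected drug harms.
Because there is no denominator of exposed patients, drug–event
associations are screened by *disproportionality*: for a drug $D$ and a
target event (a MedDRA Preferred Term, here typically autoimmune-like
hepatitis), the deduplicated reports are cross-classified as

|            | target event | other events |
|------------|:---:|:---:|
| drug $D$   | $a$ | $b$ |
| not $D$    | $c$ | $d$ |

with $N = a+b+c+d$ the whole database in the analysis window. The
package computes the four standard screening statistics from this table,
applies the conventional signal thresholds, and reports a ranked signal
table together with a descriptive profile of the event cohort.

## The four statistics

**Reporting odds ratio.**
$\mathrm{ROR} = \dfrac{a/c}{b/d}$, with
$\mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{1/a + 1/b + 1/c + 1/d}$ and the
log-normal interval $\exp(\ln \mathrm{ROR} \pm 1.96\,\mathrm{SE})$.

**Proportional reporting ratio.**
$\mathrm{PRR} = \dfrac{a/(a+b)}{c/(c+d)}$, with
$\mathrm{SE}(\ln \mathrm{PRR}) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$,
the same interval construction, and the Yates continuity-corrected
chi-square
$\chi^2 = \dfrac{N(|ad-bc| - N/2)^2}{(a+b)(c+d)(a+c)(b+d)}$, floored at
zero. Which continuity treatment the classic PRR screen uses varies
across implementations; Yates with a zero floor is the conventional
choice here.

**BCPNN information component.** The raw information component is
$\mathrm{IC} = \log_2 \dfrac{aN}{(a+b)(a+c)}$, the log observed-over-
expected co-reporting probability. The Bayesian confidence propagation
neural network places Dirichlet-type priors on the cell probabilities;
with hyperparameters $\gamma_{11}, \alpha_1, \beta_1, \alpha, \beta$ and

$$\gamma = \gamma_{11}\frac{(N+\alpha)(N+\beta)}{(a+b+\alpha_1)(a+c+\beta_1)},$$

the closed-form posterior moments are

$$E[\mathrm{IC}] = \log_2
  \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
       {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)},$$

$$V[\mathrm{IC}] = \frac{1}{(\ln 2)^2}\left[
  \frac{N-a+\gamma-\gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
  \frac{N-(a+b)+\alpha-\alpha_1}{(a+b+\alpha_1)(1+N+\alpha)} +
  \frac{N-(a+c)+\beta-\beta_1}{(a+c+\beta_1)(1+N+\beta)}
  \right],$$

and the signal bound is $\mathrm{IC}_{025} = E[\mathrm{IC}] -
2\sqrt{V[\mathrm{IC}]}$ (a two-standard-deviation normal approximation,
not Monte-Carlo posterior quantiles). The default priors
$\gamma_{11}=\alpha_1=\beta_1=1$, $\alpha=\beta=2$ make $E[\mathrm{IC}]$
exactly zero for a perfectly symmetric table — `bcpnn_stats(5, 5, 5, 5)`
returns 0 — which is the calibration property that motivates them.

A subtlety the tests document: $E[\mathrm{IC}]$ is a posterior mean, not
a literal contraction of the raw IC. For clearly associated tables
($|\mathrm{IC}| \gtrsim 1$ bit) it always lies between the raw IC and
zero, but on near-null tables its small-count bias, of order
$\log_2(1+1/a)$, can overshoot zero slightly. The property suite asserts
exact shrinkage away from the null and the bias bound everywhere.

**EBGM.** The package implements the closed-form relative-reporting
variant: $\mathrm{EBGM} = \dfrac{aN}{(a+b)(a+c)}$ with a log-normal
interval using $\mathrm{SE} = \sqrt{1/a+1/b+1/c+1/d}$, and
$\mathrm{EBGM}_{05}$ its lower bound. No gamma-mixture (MGPS) empirical
Bayes fit is performed; for the screening thresholds used here the
closed form is the quantity of interest.

## Signal thresholds

`pv_thresholds()` encodes the conventional decision rules, all strict
inequalities:

| method | rule (default) |
|---|---|
| ROR | lower 95% bound $> 1$ and $a \ge 3$ |
| PRR | lower 95% bound $> 1$ and $a \ge 3$ (alternative: PRR $> 2$ and $\chi^2 > 4$) |
| BCPNN | $\mathrm{IC}_{025} > 0$ |
| EBGM | $\mathrm{EBGM}_{05} > 2$ |

`consensus` requires all four. The PRR confidence-interval rule is the
default because it is the rule most summaries state; the
PRR-2/chi-square-4 rule is selectable (`prr_rule = "prr2_chi4"`). The
$a \ge 3$ minimum-case screen is also applied when building tables
(`min_case_filter()`), since statistics on one or two co-reports are
meaningless. No multiple-testing correction is applied: disproportionality
screening conventionally reports crude per-drug statistics, and the
package follows that practice.

As an external check, the package ships the printed top-50 signal table
of a published FAERS analysis of drug-induced autoimmune-like hepatitis
(`reference_signal_table()`); applying `classify_signals()` to the
printed statistics classifies all 50 drugs positive on all four methods,
as that analysis reports.

## Ingestion choices

FAERS quarterly extracts are dollar-delimited text in two eras: legacy
(ISR-keyed, through 2012Q3) and modern (primaryid-keyed). Both layouts
are supported; legacy rows are harmonized with `case_version = 0`.
Parsing never drops rows — unparseable dates and ages become missing.
Quarters are read one at a time and bound together, so memory scales
with a quarter, not the archive.

* **Ages** are converted to years (decades ×10, years ×1, months ÷12,
  weeks ÷52, days ÷365.25, hours ÷8766); values outside [0, 120] years
  are set to missing, since FAERS contains implausible unit-coding
  artifacts.
* **Partial dates** (YYYYMM, YYYY) resolve to the first day of the
  period.
* **Deduplication** keeps, per case, the row with the highest
  (`case_version`, `fda_receipt_date`, `primaryid`) key — the standard
  "latest version wins" rule, with receipt date and report id as
  tie-breaks.
* **Weights** coded in pounds are converted to kilograms.

## Drug-name normalization

Free-text drug strings are matched to canonical labels by exact lookup
after cleaning: case folding, punctuation removal (the `/` of
combination products is preserved), and stripping of numeric dose
tokens and a conservative stopword list of salts, dose units and
formulation words. The shipped dictionary
(`inst/extdata/drug_dictionary.tsv`, editable two-column TSV) is seeded
with the drugs of the reference signal table plus common brand and salt
synonyms; brand and generic forms of one ingredient collapse to a single
label, and combination products are single labels. Unresolved strings
are returned tagged (`NA`) and surface in `coverage_report()`, never
silently dropped. This dictionary approach replaces full NLP drug-name
standardization systems, which are out of scope; no fuzzy matching is
attempted, so coverage on real FAERS free text depends entirely on the
dictionary supplied.

## Contingency construction

Counting is report-level: a report mentioning a drug five times counts
once. By default only suspect roles (PS, SS) count as exposure —
concomitant and interacting drugs are excluded, configurable via
`roles`. The comparator is the whole deduplicated report set in the
window, not a restricted comparator series, so every drug's four cells
sum to the same $N$. No stratification by age, sex or year is performed
(the statistics are crude).

## The cohort profiler

`summarize_cohort()` reproduces the standard clinical-characteristics
table: counts with percentages at two decimals, *half-up* rounding
(`round_half_up()`; base R's round-half-to-even disagrees with printed
tables on exact `.xx5` values). Design details:

* Age bins are left-closed `[lo, hi)` — an exact boundary age falls in
  the upper bin — because the conventional printed strata ("19~45",
  "45~65") are ambiguous at the boundary; the cut points are
  configurable.
* Missing values form an explicit "unknown" level counted in the
  denominator $N$; medians and quartiles use known values only, with
  type-7 (linear interpolation) quantiles.
* Outcomes are multi-valued per report, so outcome percentages use the
  total number of outcome entries as denominator, not $N$ — this is the
  convention the reference cohort table's printed percentages imply, and
  `percent_of()` reproduces those percentages exactly.
* The top reporting countries (5 by default) are kept verbatim and the
  rest pooled as "other".
* Time to onset is event date minus the earliest suspect-drug therapy
  start; negative values and values over 20 years are treated as data
  errors and set to missing.

## The synthetic generator

`synth_generate()` emulates the joint structure of a FAERS quarter with
known ground truth so that every stage is testable without the real
database: per report, each catalog drug is mentioned independently with
its marginal probability; the target-event indicator is Bernoulli with
probability $p_0 \cdot \max_j \lambda_j$ over mentioned drugs (capped at
1), where $p_0$ is the background rate and $\lambda_j$ the planted
relative risk. The max combination (rather than a product) keeps
$\lambda$ interpretable as a per-drug risk ratio when exposures overlap.
Demographics, dates, outcomes and therapy starts are drawn independently
from a categorical model whose defaults mirror a typical hepatitis event
cohort (61% female, median age in the mid-50s, US the most frequent
reporting country, "other serious" and hospitalization the dominant
outcomes). The generator writes the modern dialect and is byte-identical
across reruns of the same configuration; `inject_duplicates()` re-emits
a deterministic sample of cases as higher versions to exercise
deduplication.

The ground-truth table records each drug's tallied cells, its planted
$\lambda$, and the *implied odds ratio*
$\frac{p_0\lambda/(1-p_0\lambda)}{p_0/(1-p_0)}$. The distinction
matters: the ROR estimates the exposure odds ratio, and when
$p_0\lambda$ is not small (e.g. $0.05$ at $\lambda = 10$,
$p_0 = 0.005$) the odds ratio exceeds $\lambda$ by several percent, so
recovery is assessed against the implied odds ratio. With several
overlapping planted drugs the recorded odds ratio is approximate (the
comparator arm is then slightly contaminated); validation plants a
single effect.

What the generator does *not* model — and therefore what passing tests
do not establish about real data: reporting trends over time, stimulated
reporting waves, masking by competing signals, correlated polypharmacy,
misspelled or free-text drug names beyond cosmetic dose/punctuation
noise, and duplicate reports that are not flagged as case versions.

## Validation design and problem sizes

The test suite validates each stage against an independent route:
contingency cells against exhaustive set-intersection enumeration on
random 20-report fixtures; ROR against a saturated logistic regression
(IRLS) on 1,000 random tables; the chi-square against
`stats::chisq.test(correct = TRUE)`; BCPNN against its calibration point
($E[\mathrm{IC}] = 0$ for the symmetric table) and hand-evaluated closed
forms; classification against the printed reference table. Monte-Carlo
checks use 20 generator runs of 200,000 reports for planted-effect
recovery (95% CI coverage of the implied odds ratio), three 100-drug
runs of 200,000 reports for null calibration of the ROR criterion
(~2.5% one-sided flag rate), and a 4,000-report end-to-end run with 10%
duplicate injection for exact cell equality between generator truth and
pipeline output. These sizes give stable estimates while keeping the
whole suite in the tens of seconds.

## Interfaces

`pv_config()` + `run_pipeline()` orchestrate
ingest → dedup → normalize → contingency → statistics → classification →
ranking, logging row counts at each stage; `write_report()` emits
diffable TSVs (`signals.tsv` with fixed column order, `top_signals.tsv`,
`cohort_summary.tsv`, `yearly_counts.tsv`). Ranking is by ROR descending
(ties by case count descending, then drug name), with frequency ranking
as an option. Configuration is plain documented R arguments rather than
a config-file format — the R constructor is itself the configuration
record, and a hash of it would add nothing for reproducibility since
outputs are deterministic in (inputs, config). A thin command-line
wrapper (`inst/cli/pv-signal.R`, subcommands `simulate` and `run`)
serves shell use.

## Known limitations

* The EBGM is the closed-form relative reporting ratio, not an MGPS
  gamma-mixture posterior; EBGM values for very sparse cells are
  accordingly less shrunk than MGPS would give.
* $\mathrm{IC}_{025}$ is the normal approximation
  $E[\mathrm{IC}] - 2\sqrt{V[\mathrm{IC}]}$, slightly anti-conservative
  for tiny $a$ relative to posterior quantiles.
* Zero cells are an error by default (the $a \ge 3$ screen avoids them
  in practice); the optional Haldane–Anscombe correction adds 0.5 to all
  four cells of affected tables and makes small-count intervals
  conservative.
* Dictionary normalization is exact-match only; real-FAERS coverage is
  bounded by the dictionary.
* Crude (unstratified) statistics only; confounding by age, sex,
  indication or era is not addressed, which is inherent to this class of
  screening methods.
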