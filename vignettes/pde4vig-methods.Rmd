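---
title: "Methods: disproportionality, sex-differential risk and time-to-onset in pde4vig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, sex-differential risk and time-to-onset in pde4vig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pde4vig)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect Individual
Case Safety Reports (ICSRs) submitted by clinicians, patients and
manufacturers. They have no denominator: we observe only who reported what,
never how many patients took a drug. The standard way to mine such data is
the *case--non-case* (disproportionality) design: for a target drug and a
target adverse event (a MedDRA Preferred Term, PT), compare how often the
event is reported with the drug against how often it is reported with every
other drug in the database. `pde4vig` packages that design end to end for
FAERS-format quarterly ASCII files, with the three marketed PDE4 inhibitors
(apremilast, crisaborole, roflumilast) as the built-in default cohorts.

## Data model and ETL

FAERS ships one `$`-delimited text file per domain and quarter: DEMO
(demographics, receipt date `FDA_DT`, onset date `EVENT_DT`), DRUG (drug
names and role codes), REAC (coded reactions) and THER (therapy start
dates). `read_faers()` parses these with a fixed `$` delimiter -- no
sniffing, so parsing is deterministic -- and a built-in alias map that
absorbs the ISR-era versus PRIMARYID-era header differences. Malformed lines
are counted and skipped, never fatal.

A case (CASEID) may be submitted repeatedly; each submission is a version
(PRIMARYID). `deduplicate_reports()` keeps, per case, the version with the
most recent complete receipt date, ties broken by the highest PRIMARYID
(numeric comparison when possible). Versions whose receipt date does not
parse to a valid calendar date can never be retained. No further
cross-version consistency filtering is applied: which "demographic
inconsistencies" real curation teams would drop is not well defined, so we
deliberately restrict ourselves to the reproducible retention rule and to
rejecting calendar-invalid dates and negative ages.

`assemble_cases()` joins DRUG/REAC/THER onto the retained version only.
Cases without any reaction record (no adverse event information) are
excluded. Cases with missing sex are kept for overall analyses and simply
fall out of the sex-stratified views; they are one dataset with a sex-known
sub-view, not two datasets.

Cohort membership (`build_cohorts()`) requires a qualifying role code
(primary suspect, `PS`, by default) and a case-insensitive word-boundary
match against a synonym set (generic plus brand names). The comparator for
each cohort is the whole deduplicated AE-bearing database minus that cohort
-- "all other drugs" -- rather than the other PDE4 cohorts, which keeps the
design a clean case--non-case contrast and makes cohort plus comparator a
partition of the database.

## The 2x2 table and the four algorithms

For each PT the table is

|              | target AE | other AEs |
|--------------|-----------|-----------|
| target drug  | a         | b         |
| other drugs  | c         | d         |

counted in **unique (case, PT) pairs**: a case reporting a PT twice
contributes once, and `b` counts the cohort's remaining case--PT pairs.
Using pair margins (rather than case margins) makes the grand total
`N = a+b+c+d` identical for every PT of a run, so all PTs of a cohort share
one consistent table universe. At the System Organ Class level the counting
unit deliberately switches to the **unique case** (see below).

The four signal statistics, evaluated literally:

* `ROR = ad/bc`, with `95% CI = exp(ln ROR ± 1.96·se)`,
  `se = sqrt(1/a + 1/b + 1/c + 1/d)` (Woolf).
* `PRR = [a/(a+b)] / [c/(c+d)]` with the uncorrected chi-squared
  `χ² = (ad−bc)²·N / [(a+b)(c+d)(a+c)(b+d)]`. No Yates continuity
  correction: the reference formula carries none.
* `IC = log2(a·N / ((a+c)(a+b)))`, the log2 observed-to-expected ratio of
  the Bayesian confidence propagation neural network (BCPNN). Its lower
  bound is the delta-method interval mapped to the log2 scale,
  `IC025 = IC − 1.96·se/ln 2`.
* `EBGM`: in the default *literal* mode, the relative reporting ratio
  `a·N / ((a+c)(a+b))` -- note `IC = log2(EBGM_literal)` identically --
  with `EBGM05 = exp(ln EBGM − 1.645·se)`. In *shrinkage* mode the
  two-component gamma-Poisson mixture of the multi-item gamma-Poisson
  shrinker (MGPS) is fitted by maximum likelihood across all tables of the
  run and the posterior geometric mean and 5th percentile are reported.
  Shrinkage needs enough tables to estimate five hyperparameters; below 100
  tables the function warns and falls back to literal mode.

**Zero cells.** The estimators are undefined when any cell is 0. We apply
the Haldane--Anscombe correction -- add 0.5 to all four cells of that table
only -- and flag the row `adjusted`. Tables without zeros are untouched.

**Positivity.** A PT is a positive signal only when *all four* algorithms
agree: `ROR` lower 95% bound > 1 with `a ≥ 2`; `PRR ≥ 2` and `χ² ≥ 4` with
`a ≥ 3`; `IC025 > 0`; `EBGM05 > 1` with `a ≥ 3`. The report-count floors
are read as conditions on the `a` cell, the conventional pharmacovigilance
interpretation of "N".

## Sex-differential risk

Sex-stratified tables are built entirely **within sex**: the male table
compares male cohort cases against male comparator cases, and likewise for
females. A pooled comparator would let sex-specific baseline reporting
(women report more overall, and different events) masquerade as a drug
effect; the within-sex comparator cancels it from each stratum's ROR.

The contrast is `log2(ROR_male / ROR_female)` tested with a Z-statistic on
the log scale, `z = (ln ROR_m − ln ROR_f) / sqrt(se_m² + se_f²)`, two-sided
normal p-values, Benjamini--Hochberg adjustment across the testable PTs of
one cohort (the FDR family is per drug). PTs with fewer than 2 target
reports in either stratum are reported but marked untestable and kept out
of the FDR family: below that floor the Z approximation is meaningless. A
PT is called *male-biased* or *female-biased* when `q < 0.05` **and**
`|log2 ratio| ≥ 1` (a two-fold ratio). The fold-change threshold is a
convention, not an estimate, and both thresholds are exposed as
configuration.

## System Organ Class aggregation

At SOC level a case reporting nausea, diarrhoea and vomiting is one
gastrointestinal case, not three signals, so `soc_tables()` counts **unique
cases**: `a` = distinct cohort cases with at least one PT in the SOC,
`b` = the remaining cohort cases, and similarly for the comparator. The
margins are therefore cohort and comparator case counts, and double-counting
bias is excluded by construction. SOC-level screening uses the ROR with its
95% CI only (not the four-algorithm rule, which is a PT-level screen);
`log2(ROR)` is the heatmap cell value, with missing (SOC, stratum)
combinations encoded as absent rather than zero.

MedDRA is licensed and cannot be redistributed, so the PT-to-SOC map is a
plain two-column CSV supplied by the user; PTs absent from the map pool
into an explicit `Unmapped` class, and the synthetic generator emits its own
consistent map.

## Time-to-onset

TTO is the calendar-day difference between adverse-event onset (`EVENT_DT`)
and therapy start, where the start date is the earliest *complete* start
date pooled from THER records first and DRUG records second (first exposure
wins when sources disagree). Three cleaning rules are applied in a fixed
order so every case carries exactly one status:

1. missing, partial (year-month or year only) or calendar-invalid dates →
   `excluded_partial`;
2. event strictly before start → `excluded_order` (same-day onset is a real
   0-day interval and is **included**);
3. interval above 7,305 days → `excluded_implausible`. Twenty years is
   stated without a day count anywhere authoritative; we fix it as
   `floor(20 × 365.25) = 7305`, with day 7,305 still included and day 7,306
   excluded.

Summaries are medians and quartiles with type-7 (linear interpolation)
quantiles, fixed explicitly because quantile conventions differ across
software and we want cross-implementation determinism. TTO is computed per
case, using the case's single onset date; FAERS does not link individual
reactions to individual onset dates, so a per-(case, PT) interval is not
identifiable from the published file structure.

## The synthetic generator

`generate_reports()` emits FAERS-format files with known structure so every
stage can be validated against ground truth. Each case independently draws:
one primary-suspect drug (categorical by market share), a true sex (per-drug
female share), and each PT as an independent Bernoulli with probability
`p_pt × enrich(drug, pt) × male_mult(drug, pt)^[sex = M]`, capped at 0.95.
Corruption knobs add duplicate versions (always with an earlier receipt
date and a lower PRIMARYID, so the correct retention is unambiguous),
missing sex, year-month-truncated dates, and event-before-start violations.
The same configuration always yields byte-identical files.

The Bernoulli formulation is chosen over a multinomial because it keeps the
estimand in closed form: expected cell counts are sums of per-case
probabilities, and `expected_ror()` returns `E[a]E[d] / (E[b]E[c])`
exactly. Cases that draw zero PTs simply carry no reaction records and are
excluded by assembly precisely like real reports lacking AE information --
they contribute to no cell, so the closed form is unaffected. PT counts per
case are not truncated; the default catalogue keeps the expectation near
1.5 PTs per case so the realized range is the typical 1--5.

Default conditions (chosen once, stated here, and used by the validation
suite): 20,000 cases; 50 PTs with background probabilities log-spaced from
0.10 to 0.005; three target drugs at 2%, 1.5% and 1% market share against a
95.5% background, mirroring the cohort-to-database proportions of a large
spontaneous-report database at desk scale; per-drug female shares 0.65,
0.66 and 0.46, emulating a drug class reported mostly by women for two
agents and mostly by men for the third; onset intervals log-normal with
median 24 days (sdlog 1.3); duplicate rate 10%, missing sex 5%, partial
dates 10%, order violations 2%. The null calibration configuration
(`sim_config_null()`) is 5,000 cases, 50 PTs, no planted effects and clean
dates.

What the generator does *not* emulate -- and what passing tests therefore
do not establish about real FAERS data: misspelled and free-text drug
names, reporting seasonality and media-driven bursts, indication
confounding (channelling), polypharmacy beyond one suspect plus an optional
concomitant, correlated PT co-reporting, and version histories that change
demographics. Results on real data inherit all the usual limitations of
spontaneous reports: no denominators, underreporting, and reporting bias.

## Calibration: what we measured

The validation suite recomputes, under the default conditions above
(problem sizes: 50-case fixtures for exact oracle comparisons; 100
replicates at 5,000 cases for null calibration; 100 replicates at 20,000
cases for recovery):

* every 2x2 table (PT and SOC level, overall and per sex) equals a
  brute-force nested-loop count, and all four statistics match independent
  direct arithmetic to 12 significant digits;
* a planted 5-fold enrichment is flagged positive and its Wald CI covers
  the closed-form expected ROR at the nominal rate;
* a planted 4:1 male:female effect on a common PT is recovered as
  male-biased with `q < 0.05`, with the mean log2-ratio estimate within
  0.25 of ground truth;
* under the null, the sex-differential test's `q < 0.05` rate stays far
  below its binomial control bound.

One calibration property deserves honest emphasis: the four-algorithm AND
is often described as conservative, but with the literal (unshrunk)
statistics it is **anticonservative for rare PTs in small cohorts**. At the
null-calibration scale (a ~100-case cohort, PTs with expected target counts
below about 1) the suite measures a false-flag rate of roughly 2.5--3% of
PTs per run, above the 2% figure one might expect; every false flag is a
small-count chance elevation (`a` between 3 and 15) whose Wald-type lower
bounds sit above the null. This is precisely the regime Bayesian shrinkage
(BCPNN credibility intervals, MGPS posteriors) was invented for; the
shrinkage EBGM mode exhibits the expected pull toward 1, but a 50-PT run is
below the 100-table floor at which the mixture fit is trustworthy, and the
IC bound here is fixed to the delta-method form. Users screening rare
events in small cohorts with the literal statistics should treat small-`a`
positives with corresponding suspicion.

## Numerical and degenerate-input choices

* Zero-cell rule as above; the `adjusted` flag is carried into all outputs.
* Deduplication tie-breaks: numeric PRIMARYID comparison whenever all tied
  ids are numeric, lexicographic otherwise; fully unparseable cases drop.
* The MGPS mixture is fitted by BFGS on log/logit-transformed
  hyperparameters from the conventional starting point
  (0.2, 0.1, 2, 4, 1/3); posterior 5th percentiles are found by `uniroot`
  on the mixture CDF with an expanding upper bracket.
* Collapsing the SOC map to a single class makes `b = 0` for every cohort
  case (every case has an AE); the zero-cell rule then applies and the
  result is flagged rather than refused.
* Empty cohorts abort table construction with a usage error; in the
  orchestrated pipeline they produce a warning, an empty output table and a
  completed run.
* All randomness flows from the single configuration seed; identical
  inputs and configuration reproduce identical CSVs byte for byte.

## Known limitations

Disproportionality cannot estimate incidence or establish causation; it
ranks reporting associations. No stratified or regression-adjusted variants
(age, year, indication) are implemented, and sex comparisons are therefore
vulnerable to confounding by indication when the user's cohorts differ in
underlying populations. The MedDRA hierarchy beyond PT→SOC (HLT, HLGT,
SMQs) is out of scope, as is parametric onset modelling (e.g. Weibull shape
analysis) -- the TTO module summarizes distributions, it does not fit
failure models.
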