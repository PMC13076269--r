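# Case--non-case disproportionality. For each preferred term the 2x2 table
#
#                 target AE   other AEs
#   target drug       a           b
#   other drugs       c           d
#
# is counted in unique (caseid, PT) pairs, so the margins a+b and c+d are the
# cohort's and comparator's case-PT pair totals and the grand total N is the
# same for every PT of a run.

#' Build per-PT 2x2 contingency tables
#'
#' Counts unique (caseid, preferred term) pairs: `a` is the number of cohort
#' cases reporting the PT, `b` the cohort's remaining case-PT pairs, and
#' `c`/`d` the analogous comparator counts. A PT reported twice by one case
#' contributes once.
#'
#' @param cohort_ids,comparator_ids Disjoint character vectors of caseids.
#' @param cases A `faers_cases` object.
#' @param min_a Minimum `a` for a PT to be returned (default 1, i.e. PTs
#'   reported at least once in the cohort).
#' @return A tibble (pt, a, b, c, d, N) with one row per PT.
#' @export
build_tables <- function(cohort_ids, comparator_ids, cases, min_a = 1L) {
  if (length(cohort_ids) == 0L) stop("empty cohort", call. = FALSE)
  if (length(intersect(cohort_ids, comparator_ids)) > 0L) {
    stop("cohort and comparator must be disjoint", call. = FALSE)
  }
  pairs <- cases$pts
  cp <- pairs[pairs$caseid %in% cohort_ids, , drop = FALSE]
  mp <- pairs[pairs$caseid %in% comparator_ids, , drop = FALSE]
  m1 <- nrow(cp)
  m0 <- nrow(mp)

  a_tab <- table(cp$pt)
  c_tab <- table(mp$pt)
  pts <- sort(unique(c(names(a_tab), names(c_tab))))
  a <- as.integer(a_tab[pts]); a[is.na(a)] <- 0L
  cc <- as.integer(c_tab[pts]); cc[is.na(cc)] <- 0L

  out <- tibble::tibble(pt = pts, a = a, b = m1 - a, c = cc, d = m0 - cc,
                        N = m1 + m0)
  out[out$a >= min_a, , drop = FALSE]
}

# Haldane--Anscombe adjustment: when any cell of a table is zero, 0.5 is
# added to all four cells of that table (the printed estimators are
# undefined at zero). Returns adjusted cells plus the per-table flag.
adjust_zero_cells <- function(a, b, c, d) {
  adj <- a == 0 | b == 0 | c == 0 | d == 0
  h <- ifelse(adj, 0.5, 0)
  list(a = a + h, b = b + h, c = c + h, d = d + h, adjusted = adj)
}

se_log_or <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/(bc); the interval is exp(ln ROR +/- 1.96 * se) with
#' se = sqrt(1/a + 1/b + 1/c + 1/d). Tables containing a zero cell are
#' evaluated after adding 0.5 to all four cells and flagged `adjusted`.
#'
#' @param a,b,c,d Numeric vectors of 2x2 cell counts (recycled together).
#' @return A tibble (ror, ror_lo95, ror_hi95, adjusted).
#' @export
ror_stats <- function(a, b, c, d) {
  z <- adjust_zero_cells(a, b, c, d)
  ror <- (z$a * z$d) / (z$b * z$c)
  hw <- 1.96 * se_log_or(z$a, z$b, z$c, z$d)
  tibble::tibble(ror = ror,
                 ror_lo95 = exp(log(ror) - hw),
                 ror_hi95 = exp(log(ror) + hw),
                 adjusted = z$adjusted)
}

#' Proportional reporting ratio and chi-squared statistic
#'
#' PRR = (a/(a+b)) / (c/(c+d)) and the (uncorrected) chi-squared statistic
#' (ad - bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d)), both evaluated on
#' zero-adjusted cells when needed.
#'
#' @inheritParams ror_stats
#' @return A tibble (prr, chi2, adjusted).
#' @export
prr_stats <- function(a, b, c, d) {
  z <- adjust_zero_cells(a, b, c, d)
  prr <- (z$a / (z$a + z$b)) / (z$c / (z$c + z$d))
  n <- z$a + z$b + z$c + z$d
  chi2 <- (z$a * z$d - z$b * z$c)^2 * n /
    ((z$a + z$b) * (z$c + z$d) * (z$a + z$c) * (z$b + z$d))
  tibble::tibble(prr = prr, chi2 = chi2, adjusted = z$adjusted)
}

#' Information component (BCPNN) with lower credibility bound
#'
#' IC = log2( a N / ((a+c)(a+b)) ), the log2 observed-to-expected reporting
#' ratio. The lower bound IC025 = IC - 1.96 * se / ln 2 uses the delta-method
#' standard error of the log odds ratio mapped to the log2 scale.
#'
#' @inheritParams ror_stats
#' @return A tibble (ic, ic025, adjusted).
#' @export
ic_stats <- function(a, b, c, d) {
  z <- adjust_zero_cells(a, b, c, d)
  n <- z$a + z$b + z$c + z$d
  ic <- log2(z$a * n / ((z$a + z$c) * (z$a + z$b)))
  ic025 <- ic - 1.96 * se_log_or(z$a, z$b, z$c, z$d) / log(2)
  tibble::tibble(ic = ic, ic025 = ic025, adjusted = z$adjusted)
}

#' Empirical Bayes geometric mean (MGPS)
#'
#' In `"literal"` mode EBGM is the relative reporting ratio
#' a N / ((a+c)(a+b)) -- the same observed-to-expected core as the
#' information component, on the natural scale -- with
#' EBGM05 = exp(ln EBGM - 1.645 * se) as the lower 5% bound. In
#' `"shrinkage"` mode the two-component gamma-Poisson mixture of the
#' multi-item gamma-Poisson shrinker is fitted by maximum likelihood over
#' all tables of the run and the posterior geometric mean and its 5th
#' percentile are reported; with fewer than 100 tables the fit is
#' unreliable, so the function warns and falls back to literal mode.
#'
#' @inheritParams ror_stats
#' @param mode `"literal"` (default) or `"shrinkage"`.
#' @return A tibble (ebgm, ebgm05, adjusted).
#' @export
ebgm_stats <- function(a, b, c, d, mode = c("literal", "shrinkage")) {
  mode <- match.arg(mode)
  if (mode == "shrinkage" && length(a) < 100L) {
    warning("shrinkage mode needs >= 100 tables; falling back to literal mode")
    mode <- "literal"
  }
  if (mode == "shrinkage") {
    n_tot <- a[1] + b[1] + c[1] + d[1]
    e_i <- (a + c) * (a + b) / n_tot
    fit <- fit_gps_mixture(a, e_i)
    sc <- gps_scores(a, e_i, fit$theta)
    return(tibble::tibble(ebgm = sc$ebgm, ebgm05 = sc$ebgm05,
                          adjusted = FALSE))
  }
  z <- adjust_zero_cells(a, b, c, d)
  n <- z$a + z$b + z$c + z$d
  ebgm <- z$a * n / ((z$a + z$c) * (z$a + z$b))
  ebgm05 <- exp(log(ebgm) - 1.645 * se_log_or(z$a, z$b, z$c, z$d))
  tibble::tibble(ebgm = ebgm, ebgm05 = ebgm05, adjusted = z$adjusted)
}

#' Compute all four signal statistics for a set of 2x2 tables
#'
#' Convenience wrapper evaluating [ror_stats()], [prr_stats()], [ic_stats()]
#' and [ebgm_stats()] on each table and applying the positivity decision of
#' [decide_signal()].
#'
#' @param tables A tibble from [build_tables()] (columns pt, a, b, c, d, N).
#' @param ebgm_mode Passed to [ebgm_stats()].
#' @return A tibble with the table counts, all point estimates and interval
#'   bounds, per-algorithm flags (`ror_pos`, `prr_pos`, `ic_pos`,
#'   `ebgm_pos`) and the combined `positive` flag.
#' @export
signal_metrics <- function(tables, ebgm_mode = c("literal", "shrinkage")) {
  ebgm_mode <- match.arg(ebgm_mode)
  out <- dplyr::bind_cols(
    tables,
    ror_stats(tables$a, tables$b, tables$c, tables$d),
    dplyr::select(prr_stats(tables$a, tables$b, tables$c, tables$d), -"adjusted"),
    dplyr::select(ic_stats(tables$a, tables$b, tables$c, tables$d), -"adjusted"),
    dplyr::select(
      ebgm_stats(tables$a, tables$b, tables$c, tables$d, mode = ebgm_mode),
      -"adjusted")
  )
  decide_signal(out)
}

#' Apply the four-algorithm positivity criterion
#'
#' A PT is a positive signal only when all four algorithms agree:
#' ROR lower 95% bound > 1 (with at least 2 target reports), PRR >= 2 with
#' chi-squared >= 4 (at least 3 target reports), IC025 > 0, and EBGM05 > 1
#' (at least 3 target reports). The report-count conditions are on the `a`
#' cell, the number of target drug-event reports.
#'
#' @param metrics A tibble with columns a, ror_lo95, prr, chi2, ic025, ebgm05.
#' @return `metrics` with logical columns ror_pos, prr_pos, ic_pos, ebgm_pos
#'   and positive added (or replaced).
#' @export
decide_signal <- function(metrics) {
  metrics$ror_pos  <- metrics$ror_lo95 > 1 & metrics$a >= 2
  metrics$prr_pos  <- metrics$prr >= 2 & metrics$chi2 >= 4 & metrics$a >= 3
  metrics$ic_pos   <- metrics$ic025 > 0
  metrics$ebgm_pos <- metrics$ebgm05 > 1 & metrics$a >= 3
  metrics$positive <- metrics$ror_pos & metrics$prr_pos & metrics$ic_pos &
    metrics$ebgm_pos
  metrics
}
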