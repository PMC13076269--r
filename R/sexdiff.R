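# Sex-stratified disproportionality: the male and female 2x2 tables for a PT
# are built entirely within each sex (male cohort vs male comparator, female
# likewise), so sex-specific baseline reporting cancels out of each ROR, and
# the male:female ROR ratio is tested on the log scale.

#' Build per-PT male and female 2x2 tables
#'
#' Cases with unknown or missing sex contribute to neither stratum. Each
#' stratum's table uses a within-sex comparator: `a_m`..`d_m` count unique
#' (caseid, PT) pairs among male cohort and male comparator cases, and
#' likewise for females.
#'
#' @inheritParams build_tables
#' @return A tibble (pt, a_m, b_m, c_m, d_m, a_f, b_f, c_f, d_f) covering
#'   every PT reported by either stratum's cohort cases.
#' @export
sex_tables <- function(cohort_ids, comparator_ids, cases) {
  demo <- cases$demo
  ids_m <- demo$caseid[!is.na(demo$sex) & demo$sex == "M"]
  ids_f <- demo$caseid[!is.na(demo$sex) & demo$sex == "F"]
  one_sex <- function(ids) {
    co <- intersect(cohort_ids, ids)
    cm <- intersect(comparator_ids, ids)
    if (length(co) == 0L) {
      return(tibble::tibble(pt = character(), a = integer(), b = integer(),
                            c = integer(), d = integer(), N = integer()))
    }
    build_tables(co, cm, cases, min_a = 0L)
  }
  tm <- one_sex(ids_m)
  tf <- one_sex(ids_f)
  out <- dplyr::full_join(
    stats::setNames(tm[c("pt", "a", "b", "c", "d")],
                    c("pt", "a_m", "b_m", "c_m", "d_m")),
    stats::setNames(tf[c("pt", "a", "b", "c", "d")],
                    c("pt", "a_f", "b_f", "c_f", "d_f")),
    by = "pt")
  # a PT absent from one stratum still has that stratum's margins
  fill_margin <- function(x, margin) ifelse(is.na(x), margin, x)
  m1m <- if (nrow(tm)) tm$a[1] + tm$b[1] else 0L
  m0m <- if (nrow(tm)) tm$c[1] + tm$d[1] else 0L
  m1f <- if (nrow(tf)) tf$a[1] + tf$b[1] else 0L
  m0f <- if (nrow(tf)) tf$c[1] + tf$d[1] else 0L
  out$a_m <- fill_margin(out$a_m, 0L); out$b_m <- fill_margin(out$b_m, m1m)
  out$c_m <- fill_margin(out$c_m, 0L); out$d_m <- fill_margin(out$d_m, m0m)
  out$a_f <- fill_margin(out$a_f, 0L); out$b_f <- fill_margin(out$b_f, m1f)
  out$c_f <- fill_margin(out$c_f, 0L); out$d_f <- fill_margin(out$d_f, m0f)
  dplyr::arrange(out, .data$pt)
}

#' Male-vs-female ROR ratio test
#'
#' For each PT computes the male and female RORs (after per-stratum
#' zero-cell adjustment), the log2 male:female ROR ratio, and a Z-test on
#' the log-transformed RORs:
#' `z = (ln ROR_m - ln ROR_f) / sqrt(se_m^2 + se_f^2)` with the usual
#' Woolf standard errors; two-sided p-values are corrected across all
#' testable PTs by Benjamini-Hochberg. PTs with fewer than `min_a` target
#' reports in either stratum are marked untestable and excluded from the
#' FDR family.
#'
#' @param tables A tibble from [sex_tables()].
#' @param min_a Per-stratum reportability floor on the `a` cells (default 2).
#' @param q_cut,lfc_cut Significance thresholds on the BH-adjusted p-value
#'   and the absolute log2 ratio used to call a direction (defaults 0.05
#'   and 1, i.e. a two-fold ratio).
#' @return A tibble with per-stratum RORs and confidence bounds,
#'   `log2_ratio`, `z`, `p`, `q`, `testable` and
#'   `direction` (`male-biased` / `female-biased` / `none`).
#' @export
ror_ratio_test <- function(tables, min_a = 2L, q_cut = 0.05, lfc_cut = 1) {
  rm_ <- ror_stats(tables$a_m, tables$b_m, tables$c_m, tables$d_m)
  rf_ <- ror_stats(tables$a_f, tables$b_f, tables$c_f, tables$d_f)
  zm <- adjust_zero_cells(tables$a_m, tables$b_m, tables$c_m, tables$d_m)
  zf <- adjust_zero_cells(tables$a_f, tables$b_f, tables$c_f, tables$d_f)
  se2 <- se_log_or(zm$a, zm$b, zm$c, zm$d)^2 +
    se_log_or(zf$a, zf$b, zf$c, zf$d)^2
  z <- (log(rm_$ror) - log(rf_$ror)) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  testable <- tables$a_m >= min_a & tables$a_f >= min_a
  q <- rep(NA_real_, length(p))
  q[testable] <- bh_adjust(p[testable])
  log2_ratio <- log2(rm_$ror / rf_$ror)
  direction <- rep("none", length(p))
  sig <- testable & !is.na(q) & q < q_cut & abs(log2_ratio) >= lfc_cut
  direction[sig & log2_ratio > 0] <- "male-biased"
  direction[sig & log2_ratio < 0] <- "female-biased"
  tibble::tibble(
    pt = tables$pt,
    a_m = tables$a_m, b_m = tables$b_m, c_m = tables$c_m, d_m = tables$d_m,
    ror_m = rm_$ror, ror_m_lo95 = rm_$ror_lo95, ror_m_hi95 = rm_$ror_hi95,
    a_f = tables$a_f, b_f = tables$b_f, c_f = tables$c_f, d_f = tables$d_f,
    ror_f = rf_$ror, ror_f_lo95 = rf_$ror_lo95, ror_f_hi95 = rf_$ror_hi95,
    log2_ratio = log2_ratio, z = z, p = p, q = q,
    testable = testable, direction = direction)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps raw p-values to false-discovery-rate adjusted q-values by the
#' step-up rule `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1
#' (delegated to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
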