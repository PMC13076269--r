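# System-organ-class aggregation. Unlike the PT-level tables, SOC-level
# tables count unique cases: a case reporting three PTs of one SOC
# contributes once to that SOC, so the margins are cohort and comparator
# case counts.

#' Read a PT-to-SOC mapping file
#'
#' MedDRA is licensed and cannot be redistributed, so the mapping from
#' preferred terms to system organ classes is a user-supplied two-column CSV
#' (`pt,soc`); the synthetic generator emits its own consistent map. PT
#' strings are normalized the same way as reaction records.
#'
#' @param path Path to a CSV with columns `pt` and `soc`.
#' @return A tibble (pt, soc).
#' @export
read_pt2soc <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pt", "soc") %in% names(map))) {
    stop("pt2soc file must have columns 'pt' and 'soc'", call. = FALSE)
  }
  map$pt <- normalize_pt(map$pt)
  dplyr::distinct(tibble::as_tibble(map[c("pt", "soc")]))
}

#' SOC-level 2x2 tables and reporting odds ratios by unique case
#'
#' For each system organ class, `a` is the number of distinct cohort cases
#' with at least one PT mapping into the SOC and `b` the remaining cohort
#' cases; `c`/`d` are the comparator analogues. Each case is counted at most
#' once per SOC however many of its PTs fall in it. PTs absent from the map
#' are pooled in class `"Unmapped"`. RORs and intervals are computed as in
#' [ror_stats()].
#'
#' @inheritParams build_tables
#' @param pt2soc A tibble (pt, soc) as from [read_pt2soc()].
#' @return A tibble (soc, a, b, c, d, ror, ror_lo95, ror_hi95, adjusted,
#'   log2_ror), one row per SOC observed in the run.
#' @export
soc_tables <- function(cohort_ids, comparator_ids, cases, pt2soc) {
  if (length(cohort_ids) == 0L) stop("empty cohort", call. = FALSE)
  if (length(intersect(cohort_ids, comparator_ids)) > 0L) {
    stop("cohort and comparator must be disjoint", call. = FALSE)
  }
  pairs <- dplyr::left_join(cases$pts, pt2soc, by = "pt")
  pairs$soc[is.na(pairs$soc)] <- "Unmapped"
  case_soc <- dplyr::distinct(pairs[c("caseid", "soc")])

  n1 <- length(cohort_ids)
  n0 <- length(comparator_ids)
  co <- case_soc[case_soc$caseid %in% cohort_ids, , drop = FALSE]
  cm <- case_soc[case_soc$caseid %in% comparator_ids, , drop = FALSE]
  a_tab <- table(co$soc)
  c_tab <- table(cm$soc)
  socs <- sort(unique(c(names(a_tab), names(c_tab))))
  a <- as.integer(a_tab[socs]); a[is.na(a)] <- 0L
  cc <- as.integer(c_tab[socs]); cc[is.na(cc)] <- 0L

  out <- tibble::tibble(soc = socs, a = a, b = n1 - a, c = cc, d = n0 - cc)
  out <- dplyr::bind_cols(out, ror_stats(out$a, out$b, out$c, out$d))
  out$log2_ror <- log2(out$ror)
  out
}

#' Assemble the SOC x stratum log2-ROR heatmap matrix
#'
#' Pivots per-stratum SOC signal tables into the matrix backing the SOC
#' heatmap: one row per SOC (sorted by name for determinism), one column per
#' stratum (e.g. drug or drug-by-sex panel), cell value `log2_ror`.
#' Combinations never observed stay `NA` (absent, not zero).
#'
#' @param soc_signals A tibble with columns `soc`, `stratum` and `log2_ror`
#'   (e.g. several [soc_tables()] results bound together with a `stratum`
#'   label).
#' @return A numeric matrix with SOC row names and stratum column names.
#' @export
heatmap_matrix <- function(soc_signals) {
  wide <- tidyr::pivot_wider(soc_signals[c("soc", "stratum", "log2_ror")],
                             names_from = "stratum", values_from = "log2_ror")
  wide <- dplyr::arrange(wide, .data$soc)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$soc
  m
}
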