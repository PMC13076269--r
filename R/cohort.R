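# Case deduplication and cohort construction. A FAERS case (CASEID) can be
# submitted in several versions (PRIMARYIDs); every analysis downstream works
# on one retained version per case.

#' Deduplicate FAERS reports by case
#'
#' Collapses multiple versions of a case to a single record: within each
#' CASEID group the version with the most recent complete FDA receipt date
#' (`fda_dt`) is retained, ties broken by the highest PRIMARYID (numeric
#' comparison when all tied ids are numeric, lexicographic otherwise).
#' Versions whose `fda_dt` does not parse as a complete date are never
#' retained; a case with no parseable version is dropped.
#'
#' @param demo A DEMO tibble as returned by [read_faers()].
#' @return A tibble with exactly one row per retained caseid.
#' @export
deduplicate_reports <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  pd <- parse_faers_date(demo$fda_dt)
  d <- demo[pd$status == "complete", , drop = FALSE]
  d$.fda <- pd$date[pd$status == "complete"]
  if (nrow(d) == 0L) {
    d$.fda <- NULL
    return(d)
  }
  dup <- d$caseid %in% d$caseid[duplicated(d$caseid)]
  singles <- d[!dup, , drop = FALSE]
  if (any(dup)) {
    multis <- d[dup, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(multis)), multis$caseid), function(i) {
      fda <- multis$.fda[i]
      i <- i[fda == max(fda)]
      i[best_primaryid(multis$primaryid[i])]
    }), use.names = FALSE)
    singles <- dplyr::bind_rows(singles, multis[sort(keep), , drop = FALSE])
  }
  singles$.fda <- NULL
  dplyr::arrange(singles, .data$caseid)
}

# index of the winning primaryid within a tie group
best_primaryid <- function(p) {
  pn <- suppressWarnings(as.numeric(p))
  if (!anyNA(pn)) which.max(pn) else which.max(rank(p, ties.method = "first"))
}

normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Assemble one case report per deduplicated case
#'
#' Joins the DRUG, REAC and THER records onto the retained version of each
#' deduplicated DEMO record (by its `primaryid`). Cases with no reaction
#' records -- reports lacking adverse event information -- are excluded.
#' Preferred terms are de-duplicated within each case; therapy start dates
#' are pooled from THER first, then from DRUG rows carrying a `start_dt`.
#'
#' @param demo A deduplicated DEMO tibble (see [deduplicate_reports()]).
#' @param drug,reac,ther Tibbles from [read_faers()]; `ther` may be `NULL`.
#' @return A `faers_cases` object: a list of linked tibbles
#'   `demo` (one row per case), `pts` (caseid, pt; distinct),
#'   `drugs` (caseid, drugname, drug_norm, role_cod) and
#'   `starts` (caseid, start_dt, source with THER before DRUG).
#' @export
assemble_cases <- function(demo, drug, reac, ther = NULL) {
  if (anyDuplicated(demo$caseid)) {
    stop("demo must be deduplicated: one row per caseid", call. = FALSE)
  }
  key <- dplyr::select(demo, "primaryid", "caseid")

  pts <- dplyr::inner_join(dplyr::select(reac, "primaryid", "pt"), key,
                           by = "primaryid")
  pts <- dplyr::distinct(dplyr::select(pts, "caseid", "pt"))
  pts <- pts[!is.na(pts$pt), , drop = FALSE]

  demo_kept <- dplyr::semi_join(demo, pts, by = "caseid")
  pts <- dplyr::semi_join(pts, demo_kept, by = "caseid")

  drugs <- dplyr::inner_join(drug, key, by = "primaryid")
  drugs <- dplyr::semi_join(drugs, demo_kept, by = "caseid")
  drugs$drug_norm <- normalize_drug_name(drugs$drugname)
  drug_tbl <- dplyr::distinct(
    dplyr::select(drugs, "caseid", "drugname", "drug_norm", "role_cod"))

  starts <- tibble::tibble(caseid = character(), start_dt = character(),
                           source = character())
  if (!is.null(ther) && nrow(ther)) {
    th <- dplyr::inner_join(dplyr::select(ther, "primaryid", "start_dt"), key,
                            by = "primaryid")
    th <- th[!is.na(th$start_dt), , drop = FALSE]
    starts <- tibble::tibble(caseid = th$caseid, start_dt = th$start_dt,
                             source = "THER")
  }
  if ("start_dt" %in% names(drugs)) {
    ds <- drugs[!is.na(drugs$start_dt), , drop = FALSE]
    starts <- dplyr::bind_rows(starts,
      tibble::tibble(caseid = ds$caseid, start_dt = ds$start_dt,
                     source = "DRUG"))
  }
  starts <- dplyr::distinct(dplyr::semi_join(starts, demo_kept, by = "caseid"))

  structure(list(demo = demo_kept, pts = pts, drugs = drug_tbl,
                 starts = starts),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$demo), " cases, ",
      nrow(x$pts), " case-PT pairs, ",
      length(unique(x$pts$pt)), " distinct PTs\n", sep = "")
  invisible(x)
}

#' Number of cases in a `faers_cases` object
#' @param cases A `faers_cases` object.
#' @export
n_cases <- function(cases) nrow(cases$demo)

#' Cohort specifications for the three PDE4 inhibitors
#'
#' Default synonym sets (generic plus US/EU brand names) used to assign
#' primary-suspect reports to the apremilast, crisaborole and roflumilast
#' cohorts. Matching is case-insensitive on word boundaries after stripping
#' punctuation, so "OTEZLA 30MG" matches the apremilast set.
#'
#' @return A named list of character vectors of drug-name synonyms.
#' @export
default_cohort_specs <- function() {
  list(
    apremilast  = c("apremilast", "otezla"),
    crisaborole = c("crisaborole", "eucrisa", "staquis"),
    roflumilast = c("roflumilast", "daliresp", "daxas", "zoryve")
  )
}

#' Build target cohorts and their comparators
#'
#' A case enters cohort *k* when any of its drug records with a qualifying
#' role code (primary suspect by default) matches any synonym of the cohort's
#' specification; the comparator for cohort *k* is every other deduplicated
#' case with at least one adverse event ("all other drugs"). A case may fall
#' in several cohorts.
#'
#' @param cases A `faers_cases` object.
#' @param specs Named list of synonym character vectors (see
#'   [default_cohort_specs()]).
#' @param role_codes Drug role codes that qualify (default `"PS"`).
#' @return A list with elements `cohorts` and `comparators` (named lists of
#'   caseid character vectors) and `membership`, a tibble (caseid, cohort).
#' @export
build_cohorts <- function(cases, specs, role_codes = "PS") {
  if (length(specs) == 0L) stop("at least one cohort spec is required", call. = FALSE)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    stop("cohort specs must be named", call. = FALSE)
  }
  dr <- cases$drugs[cases$drugs$role_cod %in% role_codes, , drop = FALSE]
  all_ids <- cases$demo$caseid
  cohorts <- lapply(specs, function(syn) {
    if (!length(syn)) stop("empty synonym set", call. = FALSE)
    pat <- paste0("\\b(", paste(vapply(normalize_drug_name(syn), escape_regex,
                                       character(1)), collapse = "|"), ")\\b")
    sort(unique(dr$caseid[grepl(pat, dr$drug_norm)]))
  })
  comparators <- lapply(cohorts, function(ids) setdiff(all_ids, ids))
  membership <- dplyr::bind_rows(lapply(names(cohorts), function(nm) {
    tibble::tibble(caseid = cohorts[[nm]], cohort = nm)
  }))
  list(cohorts = cohorts, comparators = comparators, membership = membership)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
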