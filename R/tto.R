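# Time-to-onset: days from therapy start (START_DT, THER then DRUG) to
# adverse event onset (EVENT_DT), with three cleaning rules -- incomplete
# dates, event before start, and onset beyond 20 years (7,305 days) are
# excluded.

TTO_MAX_DAYS <- 7305L   # 20 years at 365.25 days/year, floored

#' Compute time-to-onset per case
#'
#' For each case the start date is the earliest complete therapy start date
#' pooled from THER records first and DRUG records second; the event date is
#' the case's `event_dt`. Cleaning rules are applied in order so every case
#' carries exactly one status: (1) a missing/partial/invalid event or start
#' date gives `excluded_partial`; (2) an event strictly before the start
#' gives `excluded_order`; (3) an onset interval above 7,305 days (20 years)
#' gives `excluded_implausible`; otherwise the case is `included` with
#' `tto_days` the calendar-day difference. Same-day onset (0 days) is
#' included: only events strictly before the start are order violations.
#'
#' @param cases A `faers_cases` object.
#' @return A tibble (caseid, start_date, event_date, tto_days, status).
#' @export
compute_tto <- function(cases) {
  demo <- cases$demo
  ev <- parse_faers_date(demo$event_dt)

  st <- cases$starts
  spd <- parse_faers_date(st$start_dt)
  st_ok <- st[spd$status == "complete", , drop = FALSE]
  st_ok$date <- spd$date[spd$status == "complete"]
  st_ok <- st_ok[order(st_ok$caseid, st_ok$date), , drop = FALSE]
  first_start <- tibble::tibble(
    caseid = st_ok$caseid[!duplicated(st_ok$caseid)],
    start_date = st_ok$date[!duplicated(st_ok$caseid)])

  out <- tibble::tibble(caseid = demo$caseid,
                        event_date = ev$date,
                        event_complete = ev$status == "complete")
  out <- dplyr::left_join(out, first_start, by = "caseid")
  days <- as.integer(out$event_date - out$start_date)

  status <- rep("excluded_partial", nrow(out))
  have_both <- out$event_complete & !is.na(out$start_date)
  status[have_both & days < 0L] <- "excluded_order"
  status[have_both & days >= 0L & days > TTO_MAX_DAYS] <- "excluded_implausible"
  status[have_both & days >= 0L & days <= TTO_MAX_DAYS] <- "included"

  tibble::tibble(caseid = out$caseid,
                 start_date = out$start_date,
                 event_date = out$event_date,
                 tto_days = ifelse(status == "included", days, NA_integer_),
                 status = status)
}

#' Summarize an onset-time distribution
#'
#' Median and quartiles of the included onset intervals, using type-7
#' (linear interpolation) quantiles for cross-implementation determinism.
#'
#' @param records A tibble from [compute_tto()] (any mix of statuses; only
#'   `included` rows enter the summary).
#' @param cohort Optional cohort label to carry through.
#' @return A one-row tibble (cohort, n, median, q1, q3); when no record is
#'   included, `n` is 0 and the quantiles are NA.
#' @export
summarize_tto <- function(records, cohort = NA_character_) {
  x <- records$tto_days[records$status == "included"]
  if (length(x) == 0L) {
    return(tibble::tibble(cohort = cohort, n = 0L, median = NA_real_,
                          q1 = NA_real_, q3 = NA_real_))
  }
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(cohort = cohort, n = length(x), median = qs[2],
                 q1 = qs[1], q3 = qs[3])
}
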