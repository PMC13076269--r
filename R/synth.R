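# Synthetic spontaneous-report generator. Emits FAERS-format DEMO/DRUG/REAC/
# THER records with known planted structure -- drug-, sex- and organ-class-
# specific enrichment, duplicate case versions, missing demographics and
# corrupted dates -- so every pipeline stage can be checked against closed-
# form ground truth.

#' Default synthetic drug catalogue
#'
#' Three small-share target drugs against a dominant background drug. The
#' target shares (2%, 1.5%, 1%) mirror the cohort-to-database proportions of
#' a large spontaneous-report database scaled to desk size; the per-drug
#' female shares (0.65, 0.66, 0.46) emulate a class whose first two agents
#' are reported mostly by women and the third mostly by men.
#'
#' @return A tibble (name, share, p_female).
#' @export
default_drug_catalogue <- function() {
  tibble::tibble(
    name     = c("DRUG_A", "DRUG_B", "DRUG_C", "OTHER"),
    share    = c(0.020, 0.015, 0.010, 0.955),
    p_female = c(0.65, 0.66, 0.46, 0.55)
  )
}

#' Default synthetic preferred-term catalogue
#'
#' `n_pt` synthetic preferred terms (`PT_0001`, ...) with background
#' reporting probabilities log-spaced from `p_max` down to `p_min`
#' (about 1.5 expected PTs per case at the defaults, matching the 1-5 PTs
#' typical of spontaneous reports) and a synthetic organ-class label
#' (`SOC_A` ... ) cycling over `n_soc` classes.
#'
#' @param n_pt Number of preferred terms.
#' @param p_max,p_min Largest and smallest background probability.
#' @param n_soc Number of synthetic organ classes.
#' @return A tibble (pt, p, soc).
#' @export
default_pt_catalogue <- function(n_pt = 50L, p_max = 0.10, p_min = 0.005,
                                 n_soc = 8L) {
  tibble::tibble(
    pt  = sprintf("PT_%04d", seq_len(n_pt)),
    p   = exp(seq(log(p_max), log(p_min), length.out = n_pt)),
    soc = paste0("SOC_", LETTERS[(seq_len(n_pt) - 1L) %% n_soc + 1L])
  )
}

#' Simulation configuration for the synthetic report generator
#'
#' Collects every knob of the generative model. Each case independently
#' draws one primary-suspect drug (categorical by market share), a true sex
#' (per-drug female share), and each preferred term as an independent
#' Bernoulli with probability `p * enrich * male_mult^(sex == M)`, capped at
#' `prob_cap`; cases drawing no PT carry no reaction records and are later
#' excluded exactly like real reports lacking adverse event information.
#' Corruption knobs plant duplicate case versions (earlier receipt date,
#' distinct PRIMARYID), missing sex, partial dates and event-before-start
#' violations.
#'
#' @param seed Integer seed; fixes the full output byte stream.
#' @param n_cases Number of cases (default 20,000, the planted-signal
#'   validation scale).
#' @param drugs Tibble (name, share, p_female); shares must sum to 1.
#' @param pts Tibble (pt, p, soc) of background reporting probabilities.
#' @param signals Tibble (drug, pt, enrich, male_mult) of planted effects;
#'   `enrich` multiplies the PT probability for both sexes on that drug and
#'   `male_mult` additionally multiplies it for males (male:female ratio).
#' @param dup_rate Fraction of cases receiving an extra earlier version.
#' @param missing_sex_rate Fraction of cases with sex withheld.
#' @param partial_date_rate Per-date probability that a start or event date
#'   is truncated to year-month.
#' @param order_violation_rate Fraction of cases whose event date is moved
#'   before the therapy start.
#' @param conc_rate Fraction of cases with an extra concomitant drug row.
#' @param date_start,date_end Reporting window for therapy start dates.
#' @param tto_meanlog,tto_sdlog Log-normal onset-interval parameters
#'   (defaults give a median of 24 days).
#' @param prob_cap Upper cap applied to every scaled PT probability.
#' @param quarter Quarter label used for emitted file names.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 20000L,
                       drugs = default_drug_catalogue(),
                       pts = default_pt_catalogue(),
                       signals = tibble::tibble(drug = character(),
                                                pt = character(),
                                                enrich = numeric(),
                                                male_mult = numeric()),
                       dup_rate = 0.10,
                       missing_sex_rate = 0.05,
                       partial_date_rate = 0.10,
                       order_violation_rate = 0.02,
                       conc_rate = 0.30,
                       date_start = as.Date("2015-01-01"),
                       date_end = as.Date("2024-12-31"),
                       tto_meanlog = log(24),
                       tto_sdlog = 1.3,
                       prob_cap = 0.95,
                       quarter = "2025Q1") {
  cfg <- list(seed = as.integer(seed), n_cases = as.integer(n_cases),
              drugs = tibble::as_tibble(drugs), pts = tibble::as_tibble(pts),
              signals = tibble::as_tibble(signals),
              dup_rate = dup_rate, missing_sex_rate = missing_sex_rate,
              partial_date_rate = partial_date_rate,
              order_violation_rate = order_violation_rate,
              conc_rate = conc_rate,
              date_start = as.Date(date_start), date_end = as.Date(date_end),
              tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
              prob_cap = prob_cap, quarter = quarter)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 1L)
  if (abs(sum(cfg$drugs$share) - 1) > 1e-8) {
    stop("drug market shares must sum to 1", call. = FALSE)
  }
  rates <- c(cfg$dup_rate, cfg$missing_sex_rate, cfg$partial_date_rate,
             cfg$order_violation_rate, cfg$conc_rate,
             cfg$drugs$p_female, cfg$pts$p)
  if (any(rates < 0 | rates > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(cfg$signals)) {
    if (any(cfg$signals$enrich <= 0) || any(cfg$signals$male_mult <= 0)) {
      stop("signal multipliers must be positive", call. = FALSE)
    }
    if (!all(cfg$signals$drug %in% cfg$drugs$name) ||
        !all(cfg$signals$pt %in% cfg$pts$pt)) {
      stop("signals must reference catalogued drugs and PTs", call. = FALSE)
    }
  }
  if (cfg$date_end <= cfg$date_start) {
    stop("date window must be non-empty", call. = FALSE)
  }
  invisible(cfg)
}

#' Null simulation configuration
#'
#' The calibration condition: no planted signals (all multipliers 1),
#' 5,000 cases and 50 preferred terms, clean dates and no duplicates, so
#' any positive signal is a false positive.
#'
#' @param seed Integer seed.
#' @param n_cases,n_pt Scale of the null world.
#' @return A `sim_config`.
#' @export
sim_config_null <- function(seed = 1L, n_cases = 5000L, n_pt = 50L) {
  sim_config(seed = seed, n_cases = n_cases,
             pts = default_pt_catalogue(n_pt = n_pt),
             dup_rate = 0, partial_date_rate = 0, order_violation_rate = 0,
             missing_sex_rate = 0.05)
}

# Per-drug, per-sex, per-PT capped Bernoulli probability matrix implied by
# the config: the generative law shared by generate() and expected_ror().
sim_prob_array <- function(cfg) {
  drugs <- cfg$drugs$name
  pts <- cfg$pts$pt
  q <- array(rep(cfg$pts$p, each = length(drugs) * 2L),
             dim = c(length(drugs), 2L, length(pts)),
             dimnames = list(drug = drugs, sex = c("F", "M"), pt = pts))
  if (nrow(cfg$signals)) {
    for (i in seq_len(nrow(cfg$signals))) {
      g <- cfg$signals$drug[i]; j <- cfg$signals$pt[i]
      q[g, , j] <- q[g, , j] * cfg$signals$enrich[i]
      q[g, "M", j] <- q[g, "M", j] * cfg$signals$male_mult[i]
    }
  }
  pmin(q, cfg$prob_cap)
}

#' Closed-form expected reporting odds ratio under the generative model
#'
#' The estimand the pipeline's ROR converges to: the ratio of expected
#' case-PT pair counts `E[a]E[d] / (E[b]E[c])`, where the expectations
#' follow directly from the per-drug, per-sex capped Bernoulli
#' probabilities of the configuration (cases are independent, so expected
#' cell counts are sums of per-case probabilities; zero-PT cases contribute
#' nothing to any cell and thus drop out exactly as reports lacking
#' adverse events do).
#'
#' @param cfg A `sim_config`.
#' @param drug Target drug name (its cohort is the target; all other drugs
#'   form the comparator).
#' @param pt Target preferred term.
#' @param sex Optional `"F"` or `"M"` to restrict both cohort and
#'   comparator to one sex stratum.
#' @return The expected ROR (a positive scalar).
#' @export
expected_ror <- function(cfg, drug, pt, sex = NULL) {
  q <- sim_prob_array(cfg)
  drugs <- cfg$drugs$name
  sexes <- if (is.null(sex)) c("F", "M") else sex
  w <- function(g, s) {
    cfg$drugs$share[drugs == g] *
      ifelse(s == "F", cfg$drugs$p_female[drugs == g],
             1 - cfg$drugs$p_female[drugs == g])
  }
  sum_q <- apply(q, c(1, 2), sum)
  ea <- eb <- ec <- ed <- 0
  for (g in drugs) {
    for (s in sexes) {
      wa <- w(g, s)
      if (g == drug) {
        ea <- ea + wa * q[g, s, pt]
        eb <- eb + wa * (sum_q[g, s] - q[g, s, pt])
      } else {
        ec <- ec + wa * q[g, s, pt]
        ed <- ed + wa * (sum_q[g, s] - q[g, s, pt])
      }
    }
  }
  (ea * ed) / (eb * ec)
}

#' Generate a synthetic FAERS-format dataset
#'
#' Draws `cfg$n_cases` independent cases under the generative model of
#' [sim_config()], optionally writes them as `$`-delimited
#' DEMO/DRUG/REAC/THER quarterly files plus `pt2soc.csv` and
#' `ground_truth.json`, and returns the in-memory record tibbles (in the
#' same schema [read_faers()] produces) together with per-case ground
#' truth. Identical configurations yield byte-identical output.
#'
#' @param cfg A `sim_config`.
#' @param dir Optional directory; when given, files are written there.
#' @return A list with `records` (demo, drug, reac, ther tibbles),
#'   `pt2soc`, `truth` (per-case tibble: caseid, retained primaryid, drug,
#'   true and observed sex, PT count, duplicate flag, true onset days and
#'   expected onset status) and `paths` (when written).
#' @export
generate_reports <- function(cfg, dir = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_cases
  drugs <- cfg$drugs
  pts <- cfg$pts
  J <- nrow(pts)

  caseid <- sprintf("C%07d", seq_len(n))
  pid <- as.character(seq_len(n) * 10L + 5L)
  drug_idx <- sample.int(nrow(drugs), n, replace = TRUE, prob = drugs$share)
  drug <- drugs$name[drug_idx]
  sex_true <- ifelse(stats::runif(n) < drugs$p_female[drug_idx], "F", "M")
  sex_obs <- ifelse(stats::runif(n) < cfg$missing_sex_rate, NA_character_,
                    sex_true)

  q <- sim_prob_array(cfg)
  sex_i <- ifelse(sex_true == "F", 1L, 2L)
  prob <- matrix(0, n, J)
  for (g in seq_len(nrow(drugs))) {
    for (s in 1:2) {
      rows <- drug_idx == g & sex_i == s
      if (any(rows)) prob[rows, ] <- matrix(q[g, s, ], sum(rows), J,
                                            byrow = TRUE)
    }
  }
  hit <- matrix(stats::runif(n * J), n, J) < prob
  hit_idx <- which(hit, arr.ind = TRUE)
  reac <- tibble::tibble(primaryid = pid[hit_idx[, 1]],
                         pt = pts$pt[hit_idx[, 2]])
  reac <- reac[order(reac$primaryid, reac$pt), ]
  n_pts <- as.integer(rowSums(hit))

  # dates: therapy start uniform in window, onset log-normal, receipt lagged
  span <- as.integer(cfg$date_end - cfg$date_start)
  start <- cfg$date_start + floor(stats::runif(n) * (span + 1L))
  true_tto <- as.integer(round(stats::rlnorm(n, cfg$tto_meanlog,
                                             cfg$tto_sdlog)))
  event <- start + true_tto
  fda <- event + 1L + floor(stats::runif(n) * 90)

  violate <- stats::runif(n) < cfg$order_violation_rate
  back <- 1L + floor(stats::runif(n) * 30)
  event[violate] <- start[violate] - back[violate]

  part_ev <- stats::runif(n) < cfg$partial_date_rate
  part_st <- stats::runif(n) < cfg$partial_date_rate
  fmt <- function(d) format(d, "%Y%m%d")
  event_dt <- ifelse(part_ev, format(event, "%Y%m"), fmt(event))
  start_dt <- ifelse(part_st, format(start, "%Y%m"), fmt(start))

  day_diff <- as.integer(event - start)
  tto_status <- ifelse(part_ev | part_st, "excluded_partial",
                ifelse(day_diff < 0L, "excluded_order",
                ifelse(day_diff > TTO_MAX_DAYS, "excluded_implausible",
                       "included")))

  age <- ifelse(stats::runif(n) < 0.35, NA_real_,
                round(18 + stats::runif(n) * 72))

  demo <- tibble::tibble(primaryid = pid, caseid = caseid,
                         fda_dt = fmt(fda), event_dt = event_dt,
                         sex = sex_obs, age = age,
                         age_cod = ifelse(is.na(age), NA_character_, "YR"),
                         quarter = cfg$quarter)
  drug_tbl <- tibble::tibble(primaryid = pid, drugname = drug,
                             role_cod = "PS", start_dt = NA_character_)
  conc <- stats::runif(n) < cfg$conc_rate
  if (any(conc)) {
    other <- drugs$name[1L + (drug_idx[conc] %% nrow(drugs))]
    drug_tbl <- dplyr::bind_rows(drug_tbl,
      tibble::tibble(primaryid = pid[conc], drugname = other,
                     role_cod = "C", start_dt = NA_character_))
  }
  ther <- tibble::tibble(primaryid = pid, start_dt = start_dt)

  # duplicate versions: earlier receipt date, lower (numeric) primaryid, so
  # ground-truth retention is unambiguous
  dup <- stats::runif(n) < cfg$dup_rate
  if (any(dup)) {
    di <- which(dup)
    dup_pid <- as.character(di * 10L + 1L)
    dup_fda <- fda[di] - (30L + floor(stats::runif(length(di)) * 170))
    demo <- dplyr::bind_rows(demo, tibble::tibble(
      primaryid = dup_pid, caseid = caseid[di], fda_dt = fmt(dup_fda),
      event_dt = event_dt[di], sex = sex_obs[di], age = age[di],
      age_cod = ifelse(is.na(age[di]), NA_character_, "YR"),
      quarter = cfg$quarter))
    old <- stats::setNames(dup_pid, pid[di])
    remap <- function(tb) {
      sel <- tb$primaryid %in% names(old)
      extra <- tb[sel, , drop = FALSE]
      extra$primaryid <- unname(old[extra$primaryid])
      dplyr::bind_rows(tb, extra)
    }
    drug_tbl <- remap(drug_tbl)
    reac <- remap(reac)
    ther <- remap(ther)
  }
  demo <- demo[order(as.integer(demo$primaryid)), ]
  drug_tbl <- drug_tbl[order(as.integer(drug_tbl$primaryid),
                             drug_tbl$role_cod, drug_tbl$drugname), ]
  reac <- reac[order(as.integer(reac$primaryid), reac$pt), ]
  ther <- ther[order(as.integer(ther$primaryid)), ]

  truth <- tibble::tibble(
    caseid = caseid, primaryid = pid, drug = drug,
    sex_true = sex_true, sex_obs = sex_obs, n_pts = n_pts,
    has_duplicate = dup, true_tto = day_diff, tto_status = tto_status)

  out <- list(records = list(demo = demo, drug = drug_tbl, reac = reac,
                             ther = ther),
              pt2soc = pts[c("pt", "soc")], truth = truth, config = cfg)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    yq <- paste0(substr(cfg$quarter, 3, 4), "Q", substr(cfg$quarter, 6, 6))
    paths <- list(
      demo = file.path(dir, paste0("DEMO", yq, ".txt")),
      drug = file.path(dir, paste0("DRUG", yq, ".txt")),
      reac = file.path(dir, paste0("REAC", yq, ".txt")),
      ther = file.path(dir, paste0("THER", yq, ".txt")),
      pt2soc = file.path(dir, "pt2soc.csv"),
      ground_truth = file.path(dir, "ground_truth.json"))
    write_faers_file(demo[c("primaryid", "caseid", "fda_dt", "event_dt",
                            "sex", "age", "age_cod")], paths$demo)
    write_faers_file(drug_tbl, paths$drug)
    write_faers_file(reac, paths$reac)
    write_faers_file(ther, paths$ther)
    readr::write_csv(out$pt2soc, paths$pt2soc)
    jsonlite::write_json(
      list(seed = cfg$seed, n_cases = cfg$n_cases,
           signals = cfg$signals, truth = truth),
      paths$ground_truth, dataframe = "columns", na = "null")
    out$paths <- paths
  }
  out
}

# '$'-delimited writer for the FAERS ASCII dialect
write_faers_file <- function(tb, path) {
  tb <- dplyr::mutate(tb, dplyr::across(dplyr::everything(), function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }))
  lines <- c(paste(names(tb), collapse = "$"),
             do.call(paste, c(unname(as.list(tb)), sep = "$")))
  writeLines(lines, path)
  invisible(path)
}
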