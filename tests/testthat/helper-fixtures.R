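# Fixture builders and independent oracles shared across tests. The oracles
# deliberately use naive nested loops / direct arithmetic, independent of the
# package's vectorized implementations.

# Build a faers_cases object directly from a per-case description:
# a tibble with columns caseid, sex, pts (list of character), drugs
# (list of character, PS role), and optionally event_dt / start_dt.
toy_cases <- function(df) {
  n <- nrow(df)
  if (!"event_dt" %in% names(df)) df$event_dt <- rep(NA_character_, n)
  demo <- tibble::tibble(
    primaryid = as.character(seq_len(n)),
    caseid = df$caseid,
    fda_dt = rep("20240101", n),
    event_dt = df$event_dt,
    sex = df$sex,
    age = rep(NA_real_, n),
    age_cod = rep(NA_character_, n),
    quarter = rep("2024Q1", n))
  pts <- tibble::tibble(
    caseid = rep(df$caseid, lengths(df$pts)),
    pt = unlist(df$pts, use.names = FALSE))
  pts <- dplyr::distinct(pts)
  drugs <- tibble::tibble(
    caseid = rep(df$caseid, lengths(df$drugs)),
    drugname = unlist(df$drugs, use.names = FALSE),
    role_cod = "PS")
  drugs$drug_norm <- pde4vig:::normalize_drug_name(drugs$drugname)
  starts <- if ("start_dt" %in% names(df)) {
    tibble::tibble(caseid = df$caseid, start_dt = df$start_dt,
                   source = "THER")
  } else {
    tibble::tibble(caseid = character(), start_dt = character(),
                   source = character())
  }
  starts <- starts[!is.na(starts$start_dt), , drop = FALSE]
  structure(list(demo = demo, pts = pts,
                 drugs = drugs[c("caseid", "drugname", "drug_norm",
                                 "role_cod")],
                 starts = starts),
            class = "faers_cases")
}

# Brute-force nested-loop 2x2 tables in case-PT pair units.
oracle_pt_tables <- function(cohort_ids, comparator_ids, cases) {
  pair_list <- split(cases$pts$pt, cases$pts$caseid)
  all_pts <- sort(unique(cases$pts$pt))
  rows <- list()
  for (pt in all_pts) {
    a <- b <- cc <- d <- 0L
    for (cid in names(pair_list)) {
      pts_here <- unique(pair_list[[cid]])
      in_cohort <- cid %in% cohort_ids
      in_comp <- cid %in% comparator_ids
      for (p in pts_here) {
        if (in_cohort) {
          if (p == pt) a <- a + 1L else b <- b + 1L
        } else if (in_comp) {
          if (p == pt) cc <- cc + 1L else d <- d + 1L
        }
      }
    }
    rows[[pt]] <- data.frame(pt = pt, a = a, b = b, c = cc, d = d)
  }
  out <- do.call(rbind, rows)
  out$N <- out$a + out$b + out$c + out$d
  tibble::as_tibble(out)
}

# Brute-force SOC tables in unique-case units.
oracle_soc_tables <- function(cohort_ids, comparator_ids, cases, pt2soc) {
  soc_of <- stats::setNames(pt2soc$soc, pt2soc$pt)
  pair_list <- split(cases$pts$pt, cases$pts$caseid)
  case_socs <- lapply(pair_list, function(p) {
    s <- unname(soc_of[unique(p)])
    s[is.na(s)] <- "Unmapped"
    unique(s)
  })
  all_socs <- sort(unique(unlist(case_socs)))
  rows <- lapply(all_socs, function(soc) {
    a <- sum(vapply(cohort_ids, function(cid) {
      soc %in% case_socs[[cid]]
    }, logical(1)))
    cc <- sum(vapply(comparator_ids, function(cid) {
      cid %in% names(case_socs) && soc %in% case_socs[[cid]]
    }, logical(1)))
    data.frame(soc = soc, a = a, b = length(cohort_ids) - a,
               c = cc, d = length(comparator_ids) - cc)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# Direct-arithmetic signal statistics (independent of the package path).
oracle_stats <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  n <- a + b + c + d
  ror <- (a * d) / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
  ic <- log2(a * n / ((a + c) * (a + b)))
  ebgm <- a * n / ((a + c) * (a + b))
  list(ror = ror, ror_lo95 = exp(log(ror) - 1.96 * se),
       ror_hi95 = exp(log(ror) + 1.96 * se),
       prr = prr, chi2 = chi2,
       ic = ic, ic025 = ic - 1.96 * se / log(2),
       ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.645 * se))
}

# Hand-evaluated Benjamini-Hochberg step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  if (m > 1) {
    for (i in (m - 1):1) {
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    }
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

expect_rel_equal <- function(x, y, tol = 1e-12) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1e-300)),
              label = paste0("relative difference within ", tol))
}

# Write a faers file set from raw record tibbles into a temp dir.
write_fixture_files <- function(records, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pde4vig:::write_faers_file(
    records$demo[c("primaryid", "caseid", "fda_dt", "event_dt", "sex",
                   "age", "age_cod")],
    file.path(dir, "DEMO24Q1.txt"))
  pde4vig:::write_faers_file(records$drug, file.path(dir, "DRUG24Q1.txt"))
  pde4vig:::write_faers_file(records$reac, file.path(dir, "REAC24Q1.txt"))
  pde4vig:::write_faers_file(records$ther, file.path(dir, "THER24Q1.txt"))
  dir
}

# Full desk-scale pipeline on in-memory generator records: deduplicate,
# assemble, split into the target-drug cohort and its comparator.
run_synth_pipeline <- function(cfg, target = "DRUG_A") {
  g <- generate_reports(cfg)
  dd <- deduplicate_reports(g$records$demo)
  cs <- assemble_cases(dd, g$records$drug, g$records$reac, g$records$ther)
  ch <- build_cohorts(cs, stats::setNames(list(target), "target"))
  list(g = g, cases = cs, cohort = ch$cohorts$target,
       comparator = ch$comparators$target)
}
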