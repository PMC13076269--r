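demo_row <- function(caseid, primaryid, fda_dt) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 fda_dt = fda_dt, event_dt = NA_character_,
                 sex = NA_character_, age = NA_real_,
                 age_cod = NA_character_, quarter = NA_character_)
}

test_that("deduplication keeps the most recent receipt date", {
  demo <- dplyr::bind_rows(demo_row(100, 1, "20200101"),
                           demo_row(100, 2, "20200301"))
  out <- deduplicate_reports(demo)
  expect_equal(out$primaryid, "2")
})

test_that("single-version cases pass through unchanged", {
  demo <- demo_row(7, 70, "20210515")
  expect_equal(as.data.frame(deduplicate_reports(demo)), as.data.frame(demo))
})

test_that("receipt-date ties break on the highest numeric primaryid", {
  demo <- dplyr::bind_rows(demo_row(200, 7, "20200101"),
                           demo_row(200, 12, "20200101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "12")
})

test_that("unparseable receipt dates lose; fully unparseable cases drop", {
  demo <- dplyr::bind_rows(demo_row(1, 9, "202003"),      # partial, loses
                           demo_row(1, 2, "20200101"),
                           demo_row(2, 5, "bogus"))       # whole case drops
  out <- deduplicate_reports(demo)
  expect_equal(out$caseid, "1")
  expect_equal(out$primaryid, "2")
})

test_that("deduplication matches a brute-force sort on random fixtures", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 40
    demo <- demo_row(sample(1:12, n, replace = TRUE),
                     sample(1:999, n),
                     sprintf("2020%02d%02d", sample(1:12, n, TRUE),
                             sample(1:28, n, TRUE)))
    out <- deduplicate_reports(demo)
    # oracle: per caseid, sort all versions by (fda date, numeric pid)
    expected <- vapply(split(demo, demo$caseid), function(g) {
      g <- g[order(as.Date(g$fda_dt, "%Y%m%d"),
                   as.numeric(g$primaryid)), ]
      g$primaryid[nrow(g)]
    }, character(1))
    expect_equal(sort(out$primaryid), sort(unname(expected)))
    # idempotence and order invariance
    expect_equal(as.data.frame(deduplicate_reports(out)), as.data.frame(out))
    shuffled <- demo[sample(nrow(demo)), ]
    expect_equal(as.data.frame(deduplicate_reports(shuffled)),
                 as.data.frame(out))
  }
})

test_that("assembly de-duplicates PTs and drops cases lacking reactions", {
  demo <- dplyr::bind_rows(demo_row(1, 10, "20200101"),
                           demo_row(2, 20, "20200101"),
                           demo_row(3, 30, "20200101"))
  drug <- tibble::tibble(primaryid = c("10", "20", "30"),
                         drugname = "apremilast", role_cod = "PS",
                         start_dt = NA_character_)
  reac <- tibble::tibble(primaryid = c("10", "10", "20"),
                         pt = c("NAUSEA", "NAUSEA", "HEADACHE"))
  cs <- assemble_cases(demo, drug, reac)
  expect_equal(n_cases(cs), 2L)                      # case 3 has no AE
  expect_equal(cs$pts$pt[cs$pts$caseid == "1"], "NAUSEA")
  expect_false("3" %in% cs$demo$caseid)
})

test_that("therapy start dates pool THER before DRUG", {
  demo <- demo_row(1, 10, "20200101")
  drug <- tibble::tibble(primaryid = "10", drugname = "x", role_cod = "PS",
                         start_dt = "20200301")
  reac <- tibble::tibble(primaryid = "10", pt = "NAUSEA")
  ther <- tibble::tibble(primaryid = "10", start_dt = "20200201")
  cs <- assemble_cases(demo, drug, reac, ther)
  expect_equal(cs$starts$source, c("THER", "DRUG"))
  expect_equal(cs$starts$start_dt, c("20200201", "20200301"))
})

test_that("joins use the retained version's primaryid only", {
  demo <- dplyr::bind_rows(demo_row(1, 1, "20200101"),
                           demo_row(1, 2, "20200301"))
  dedup <- deduplicate_reports(demo)
  reac <- tibble::tibble(primaryid = c("1", "2"),
                         pt = c("OLD VERSION PT", "NAUSEA"))
  drug <- tibble::tibble(primaryid = c("1", "2"), drugname = "x",
                         role_cod = "PS", start_dt = NA_character_)
  cs <- assemble_cases(dedup, drug, reac)
  expect_equal(cs$pts$pt, "NAUSEA")
})

test_that("cohort matching follows synonyms, roles and word boundaries", {
  df <- tibble::tibble(
    caseid = as.character(1:10),
    sex = rep(c("F", "M"), 5),
    pts = rep(list("PT_X"), 10),
    drugs = list("OTEZLA 30MG", "aspirin", "Apremilast", "ibuprofen",
                 "metformin", "apremilastol", "statin", "warfarin",
                 "OTEZLA", "lisinopril"))
  cs <- toy_cases(df)
  ch <- build_cohorts(cs, list(apremilast = c("apremilast", "otezla")))
  # apremilastol must NOT match (word boundary); 1, 3, 9 match
  expect_equal(ch$cohorts$apremilast, c("1", "3", "9"))
  expect_equal(length(ch$comparators$apremilast), 7L)
  expect_setequal(c(ch$cohorts$apremilast, ch$comparators$apremilast),
                  cs$demo$caseid)
})

test_that("non-suspect roles never place a case in a cohort", {
  demo <- demo_row(1, 10, "20200101")
  drug <- tibble::tibble(primaryid = "10", drugname = "apremilast",
                         role_cod = "C", start_dt = NA_character_)
  reac <- tibble::tibble(primaryid = "10", pt = "NAUSEA")
  cs <- assemble_cases(demo, drug, reac)
  ch <- build_cohorts(cs, list(apremilast = "apremilast"))
  expect_equal(length(ch$cohorts$apremilast), 0L)
  expect_equal(ch$comparators$apremilast, "1")
})

test_that("empty cohort specifications are a usage error", {
  cs <- toy_cases(tibble::tibble(caseid = "1", sex = "F",
                                 pts = list("X"), drugs = list("d")))
  expect_error(build_cohorts(cs, list()), "at least one")
  expect_error(build_cohorts(cs, list(a = character())), "empty synonym")
})

test_that("cohort plus comparator always partition the assembled cases", {
  set.seed(33)
  cfg <- sim_config(seed = 5, n_cases = 800)
  g <- generate_reports(cfg)
  cs <- assemble_cases(deduplicate_reports(g$records$demo),
                       g$records$drug, g$records$reac, g$records$ther)
  ch <- build_cohorts(cs, list(a = "DRUG_A", b = "DRUG_B", c = "DRUG_C"))
  for (nm in names(ch$cohorts)) {
    expect_equal(length(ch$cohorts[[nm]]) + length(ch$comparators[[nm]]),
                 n_cases(cs))
    expect_length(intersect(ch$cohorts[[nm]], ch$comparators[[nm]]), 0L)
  }
})
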