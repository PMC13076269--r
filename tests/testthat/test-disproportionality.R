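test_that("minimal contingency tables count unique case-PT pairs", {
  cs <- toy_cases(tibble::tibble(
    caseid = c("1", "2"), sex = c("F", "M"),
    pts = list("X", "X"), drugs = list("target", "other")))
  tb <- build_tables("1", "2", cs)
  expect_equal(tb$a, 1L)
  expect_equal(tb$b, 0L)
  expect_equal(tb$c, 1L)
  expect_equal(tb$d, 0L)
})

test_that("a PT listed twice by one case contributes once", {
  cs <- toy_cases(tibble::tibble(
    caseid = c("1", "2"), sex = c("F", "M"),
    pts = list(c("X", "X", "Y"), "X"), drugs = list("t", "o")))
  tb <- build_tables("1", "2", cs)
  expect_equal(tb$a[tb$pt == "X"], 1L)
  expect_equal(tb$b[tb$pt == "X"], 1L)   # the Y pair
})

test_that("tables equal brute-force nested-loop counts on toy fixtures", {
  set.seed(5)
  for (rep in 1:4) {
    n <- 5 + rep * 10
    df <- tibble::tibble(
      caseid = as.character(seq_len(n)),
      sex = sample(c("F", "M"), n, TRUE),
      pts = lapply(seq_len(n), function(i) {
        sample(paste0("PT_", 1:6), sample(1:4, 1))
      }),
      drugs = as.list(sample(c("t", "o1", "o2"), n, TRUE,
                             prob = c(0.3, 0.4, 0.3))))
    cs <- toy_cases(df)
    ch <- build_cohorts(cs, list(t = "t"))
    tb <- build_tables(ch$cohorts$t, ch$comparators$t, cs, min_a = 0L)
    oracle <- oracle_pt_tables(ch$cohorts$t, ch$comparators$t, cs)
    merged <- dplyr::inner_join(tb, oracle, by = "pt",
                                suffix = c("", "_o"))
    expect_equal(nrow(merged), nrow(oracle))
    expect_equal(merged$a, merged$a_o)
    expect_equal(merged$b, merged$b_o)
    expect_equal(merged$c, merged$c_o)
    expect_equal(merged$d, merged$d_o)
    expect_true(all(tb$a + tb$b + tb$c + tb$d == tb$N))
    expect_equal(length(unique(tb$N)), 1L)   # N constant across PTs
  }
})

test_that("empty or overlapping cohorts are usage errors", {
  cs <- toy_cases(tibble::tibble(caseid = c("1", "2"), sex = c("F", "M"),
                                 pts = list("X", "Y"),
                                 drugs = list("t", "o")))
  expect_error(build_tables(character(), "2", cs), "empty cohort")
  expect_error(build_tables("1", c("1", "2"), cs), "disjoint")
})

test_that("ROR matches direct arithmetic", {
  r <- ror_stats(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_true(r$ror_lo95 < 1 && r$ror_hi95 > 1)
  expect_false(r$adjusted)

  r2 <- ror_stats(20, 80, 100, 9900)
  expect_equal(r2$ror, 24.75)
  o <- oracle_stats(20, 80, 100, 9900)
  expect_equal(r2$ror_lo95, o$ror_lo95)
  expect_equal(r2$ror_hi95, o$ror_hi95)
})

test_that("zero cells trigger the Haldane-Anscombe adjustment with a flag", {
  r <- ror_stats(0, 10, 10, 100)
  expect_true(r$adjusted)
  o <- oracle_stats(0, 10, 10, 100)   # evaluates on (0.5, 10.5, 10.5, 100.5)
  expect_equal(r$ror, o$ror)
  expect_equal(r$ror_lo95, o$ror_lo95)
})

test_that("PRR and chi-squared match the printed formulas", {
  r <- prr_stats(1, 9, 10, 90)
  expect_equal(r$prr, 1)
  expect_equal(r$chi2, 0)

  r2 <- prr_stats(10, 90, 100, 9900)
  expect_equal(r2$prr, 10)
  o <- oracle_stats(10, 90, 100, 9900)
  expect_equal(r2$chi2, o$chi2)
  expect_equal(r2$chi2, 74.4497, tolerance = 1e-4)
})

test_that("information component matches direct arithmetic", {
  # independence: a*N == (a+c)(a+b)
  r0 <- ic_stats(10, 90, 100, 900)
  expect_equal(r0$ic, 0)

  r <- ic_stats(10, 90, 100, 9900)
  expect_equal(r$ic, log2(10 * 10100 / (110 * 100)))
  expect_equal(r$ic, 3.1989, tolerance = 1e-4)
  expect_true(all(ic_stats(c(1, 5, 50), c(9, 5, 100), c(3, 8, 40),
                           c(100, 80, 4000))$ic025 <
                  ic_stats(c(1, 5, 50), c(9, 5, 100), c(3, 8, 40),
                           c(100, 80, 4000))$ic))
})

test_that("literal EBGM is the relative reporting ratio", {
  expect_equal(ebgm_stats(10, 90, 100, 900)$ebgm, 1)
  r <- ebgm_stats(10, 90, 100, 9900)
  expect_equal(r$ebgm, 9.1818, tolerance = 1e-4)
  o <- oracle_stats(10, 90, 100, 9900)
  expect_equal(r$ebgm05, o$ebgm05)
})

test_that("ic equals log2 of literal ebgm for random tables", {
  set.seed(99)
  n <- 10000
  a <- rpois(n, 5); b <- rpois(n, 50); c <- rpois(n, 40); d <- rpois(n, 2000)
  ic <- ic_stats(a, b, c, d)$ic
  ebgm <- ebgm_stats(a, b, c, d)$ebgm
  expect_rel_equal(ic, log2(ebgm), tol = 1e-12)
})

test_that("ROR approaches PRR for rare events", {
  set.seed(17)
  a <- sample(1:5, 50, TRUE)
  b <- sample(5000:20000, 50, TRUE)
  c <- sample(1:50, 50, TRUE)
  d <- sample(5e5:2e6, 50, TRUE)
  ror <- ror_stats(a, b, c, d)$ror
  prr <- prr_stats(a, b, c, d)$prr
  expect_true(all(abs(ror - prr) / prr < 0.01))
})

test_that("all four statistics increase strictly with a", {
  a <- 1:30
  r <- ror_stats(a, 100, 50, 5000)$ror
  p <- prr_stats(a, 100, 50, 5000)$prr
  i <- ic_stats(a, 100, 50, 5000)$ic
  e <- ebgm_stats(a, 100, 50, 5000)$ebgm
  for (x in list(r, p, i, e)) expect_true(all(diff(x) > 0))
})

test_that("the four-criteria decision follows the thresholds", {
  strong <- signal_metrics(tibble::tibble(
    pt = "X", a = 50L, b = 50L, c = 50L, d = 9850L, N = 10000L))
  expect_true(strong$positive)
  expect_true(all(strong$ror_pos, strong$prr_pos, strong$ic_pos,
                  strong$ebgm_pos))

  # a = 2 with a huge ROR still fails PRR/EBGM report-count floors
  tiny <- signal_metrics(tibble::tibble(
    pt = "X", a = 2L, b = 1L, c = 2L, d = 10000L, N = 10005L))
  expect_true(tiny$ror_pos)
  expect_false(tiny$prr_pos)
  expect_false(tiny$ebgm_pos)
  expect_false(tiny$positive)

  null <- signal_metrics(tibble::tibble(
    pt = "X", a = 10L, b = 90L, c = 100L, d = 900L, N = 1100L))
  expect_false(null$positive)
})

test_that("positive implies every per-algorithm flag", {
  set.seed(3)
  m <- signal_metrics(tibble::tibble(
    pt = paste0("P", 1:200),
    a = rpois(200, 4), b = rpois(200, 60),
    c = rpois(200, 40), d = rpois(200, 3000)) |>
      dplyr::mutate(N = a + b + c + d))
  expect_true(all(!m$positive |
                  (m$ror_pos & m$prr_pos & m$ic_pos & m$ebgm_pos)))
  expect_true(all(m$ror_lo95 <= m$ror & m$ror <= m$ror_hi95))
})

test_that("shrinkage mode warns and falls back below 100 tables", {
  expect_warning(r <- ebgm_stats(5, 50, 40, 2000, mode = "shrinkage"),
                 "100 tables")
  expect_equal(r$ebgm, ebgm_stats(5, 50, 40, 2000)$ebgm)
})

test_that("shrinkage pulls null tables toward 1 harder than literal mode", {
  set.seed(42)
  n_tab <- 400
  # null world: a ~ Poisson(E) around its expectation
  e <- runif(n_tab, 1, 30)
  n_tot <- 5e4
  a <- rpois(n_tab, e)
  row_m <- round(e * 50)               # a+b margin
  col_m <- pmax(round(e * n_tot / row_m), a)
  b <- pmax(row_m - a, 1)
  c <- pmax(col_m - a, 1)
  d <- pmax(n_tot - a - b - c, 1)
  lit <- ebgm_stats(a, b, c, d, mode = "literal")$ebgm
  shr <- ebgm_stats(a, b, c, d, mode = "shrinkage")$ebgm
  expect_lt(abs(log(stats::median(shr))), abs(log(stats::median(lit))) + 0.05)
  expect_lt(stats::mad(log(shr)), stats::mad(log(lit)))
})
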