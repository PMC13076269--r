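# Reading FAERS quarterly ASCII files ('$'-delimited, one record per line).
# The delimiter is fixed to '$' -- the FAERS ASCII dialect -- with no sniffing,
# so parsing is deterministic across quarters.

# Column-name synonyms across FAERS eras (ISR-era vs PRIMARYID-era headers).
.faers_aliases <- list(
  primaryid = c("primaryid", "isr"),
  caseid    = c("caseid", "case", "case_num"),
  fda_dt    = c("fda_dt"),
  event_dt  = c("event_dt"),
  sex       = c("sex", "gndr_cod"),
  age       = c("age"),
  age_cod   = c("age_cod"),
  drugname  = c("drugname", "drug_name"),
  role_cod  = c("role_cod", "role_code"),
  pt        = c("pt"),
  start_dt  = c("start_dt")
)

.faers_schema <- list(
  DEMO = list(required = c("primaryid", "caseid", "fda_dt"),
              optional = c("event_dt", "sex", "age", "age_cod")),
  DRUG = list(required = c("primaryid", "drugname", "role_cod"),
              optional = "start_dt"),
  REAC = list(required = c("primaryid", "pt"), optional = character()),
  THER = list(required = c("primaryid", "start_dt"), optional = character())
)

#' Read FAERS quarterly ASCII files
#'
#' Parses one or more `$`-delimited FAERS quarterly files of a single kind
#' (DEMO, DRUG, REAC or THER) into a tibble with canonical column names.
#' Column headers are matched case-insensitively through a built-in alias map
#' covering both the ISR-era and PRIMARYID-era layouts; unknown extra columns
#' are ignored. Lines whose field count does not match the header are counted
#' as malformed and skipped, never fatal.
#'
#' @param paths Character vector of file paths, all of the same kind.
#' @param kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`.
#' @return A tibble of records; one row per well-formed data line. The
#'   attribute `n_malformed` carries the total count of skipped lines.
#'   DEMO rows gain a `quarter` label parsed from the file name when it
#'   follows the `DEMOyyQq` convention, and `sex` normalized to
#'   `F`/`M`/`UNK`/`NA`. REAC preferred terms are whitespace-normalized and
#'   upper-cased; empty PTs are dropped (and counted as malformed).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("primaryid$caseid$fda_dt$event_dt$sex",
#'              "1001$100$20200301$20200115$F"), f)
#' read_faers(f, "DEMO")
#' @export
read_faers <- function(paths, kind = c("DEMO", "DRUG", "REAC", "THER")) {
  kind <- match.arg(kind)
  parts <- lapply(paths, read_faers_one, kind = kind)
  out <- dplyr::bind_rows(lapply(parts, function(p) p$records))
  attr(out, "n_malformed") <- sum(vapply(parts, function(p) p$n_malformed, integer(1)))
  out
}

read_faers_one <- function(path, kind) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("FAERS format error: '", path, "' has no header row", call. = FALSE)
  }
  # A trailing '$' delimits an empty final field; strsplit would silently drop
  # it, so a sentinel byte is appended before splitting and stripped after.
  split_line <- function(x) {
    if (length(x) == 0L) return(list())
    p <- strsplit(paste0(x, "\x01"), "$", fixed = TRUE)
    lapply(p, function(f) {
      f[length(f)] <- sub("\x01$", "", f[length(f)])
      f
    })
  }
  header <- tolower(trimws(split_line(lines[1])[[1]]))
  ncol_header <- length(header)

  schema <- .faers_schema[[kind]]
  col_idx <- vapply(c(schema$required, schema$optional), function(canon) {
    hit <- which(header %in% .faers_aliases[[canon]])
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  missing_req <- schema$required[is.na(col_idx[schema$required])]
  if (length(missing_req)) {
    stop("FAERS format error: '", path, "' does not look like a ", kind,
         " file (missing column(s): ", paste(missing_req, collapse = ", "), ")",
         call. = FALSE)
  }

  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- split_line(body)
  ok <- lengths(fields) == ncol_header
  n_malformed <- sum(!ok)
  fields <- fields[ok]

  grab <- function(canon) {
    i <- col_idx[[canon]]
    if (is.na(i)) rep(NA_character_, length(fields))
    else trimws(vapply(fields, `[[`, character(1), i))
  }
  rec <- tibble::as_tibble(stats::setNames(
    lapply(names(col_idx), grab), names(col_idx)))
  rec[rec == ""] <- NA_character_

  if (kind == "DEMO") {
    rec$sex <- normalize_sex(rec$sex)
    age <- suppressWarnings(as.numeric(rec$age))
    age[!is.na(age) & age < 0] <- NA_real_   # negative ages are implausible
    rec$age <- age
    rec$quarter <- quarter_from_filename(path)
  }
  if (kind == "DRUG") {
    rc <- toupper(trimws(rec$role_cod))
    rc[!rc %in% c("PS", "SS", "C", "I")] <- NA_character_
    rec$role_cod <- rc
  }
  if (kind == "REAC") {
    rec$pt <- normalize_pt(rec$pt)
    bad_pt <- is.na(rec$pt)
    n_malformed <- n_malformed + sum(bad_pt)
    rec <- rec[!bad_pt, , drop = FALSE]
  }
  drop_key <- is.na(rec$primaryid)
  if (kind == "DEMO") drop_key <- drop_key | is.na(rec$caseid)
  n_malformed <- n_malformed + sum(drop_key)
  rec <- rec[!drop_key, , drop = FALSE]

  list(records = rec, n_malformed = n_malformed)
}

normalize_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- ifelse(is.na(x) | x == "", NA_character_,
                ifelse(x == "F", "F", ifelse(x == "M", "M", "UNK")))
  out
}

normalize_pt <- function(x) {
  x <- toupper(gsub("\\s+", " ", trimws(x)))
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

quarter_from_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("([0-9]{2})[Qq]([1-4])", basename(path)))
  if (!length(m)) return(NA_character_)
  yy <- as.integer(substr(m, 1, 2))
  paste0(ifelse(yy < 50, 2000 + yy, 1900 + yy), "Q", substr(m, 4, 4))
}

#' Parse a FAERS raw date string
#'
#' FAERS date fields are plain digit strings. An 8-digit `YYYYMMDD` string
#' that forms a valid calendar date is `complete`; a 6-digit `YYYYMM` with a
#' valid month, or a bare 4-digit `YYYY`, is `partial` (month or day
#' missing); anything else -- including impossible dates such as month 13 --
#' is `invalid`. The function is total over character vectors: the three
#' statuses partition all inputs.
#'
#' @param x Character vector of raw date strings (NA allowed).
#' @return A tibble with columns `status` (`complete`/`partial`/`invalid`)
#'   and `date` (a `Date`, NA unless complete).
#' @examples
#' parse_faers_date(c("20200115", "202001", "20201340"))
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  n <- length(x)
  status <- rep("invalid", n)
  date <- rep(as.Date(NA), n)

  is8 <- grepl("^[0-9]{8}$", x)
  is6 <- grepl("^[0-9]{6}$", x)
  is4 <- grepl("^[0-9]{4}$", x)

  if (any(is8)) {
    y <- as.integer(substr(x[is8], 1, 4))
    m <- as.integer(substr(x[is8], 5, 6))
    d <- as.integer(substr(x[is8], 7, 8))
    ok <- m >= 1 & m <= 12 & d >= 1 & d <= days_in_month(y, m)
    status[is8][ok] <- "complete"
    date[is8][ok] <- as.Date(sprintf("%04d-%02d-%02d", y[ok], m[ok], d[ok]))
  }
  if (any(is6)) {
    m6 <- as.integer(substr(x[is6], 5, 6))
    status[is6][m6 >= 1 & m6 <= 12] <- "partial"
  }
  status[is4] <- "partial"
  tibble::tibble(status = status, date = date)
}

days_in_month <- function(y, m) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  d <- base[pmin(pmax(m, 1L), 12L)]
  d[m == 2L & leap] <- 29L
  d
}

#' Write a result table as CSV
#'
#' All pipeline outputs are written as comma-separated UTF-8 text with a
#' header row; fields containing commas are quoted, so string and numeric
#' columns round-trip losslessly through [read_table()].
#'
#' @param rows A data frame of results sharing one schema.
#' @param path Destination file path.
#' @return `rows`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(rows, path, na = "")
  invisible(rows)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
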