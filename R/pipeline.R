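# End-to-end orchestration: read -> deduplicate -> assemble -> cohorts ->
# PT signals -> sex-differential tests -> SOC aggregation -> time-to-onset
# -> figures, with per-stage record counts logged and written alongside the
# result tables. Re-running on identical inputs reproduces identical CSVs.

#' Pipeline run configuration
#'
#' @param input_dir Directory containing FAERS quarterly ASCII files
#'   (`DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`, optionally `THER*.txt`).
#' @param output_dir Directory for result CSVs, metadata and figures.
#' @param cohorts Named list of drug-name synonym vectors
#'   (default [default_cohort_specs()]).
#' @param pt2soc Path to a `pt,soc` CSV, or a tibble, or `NULL` to pool all
#'   PTs into one unmapped class.
#' @param ebgm_mode `"literal"` or `"shrinkage"` (see [ebgm_stats()]).
#' @param role_codes Drug role codes forming a cohort (default `"PS"`).
#' @param q_cut,lfc_cut Sex-difference significance thresholds.
#' @param make_plots Emit figure files (PDF, plus PNG where a raster device
#'   is available).
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       cohorts = default_cohort_specs(),
                       pt2soc = NULL,
                       ebgm_mode = "literal",
                       role_codes = "PS",
                       q_cut = 0.05, lfc_cut = 1,
                       make_plots = TRUE) {
  stopifnot(dir.exists(input_dir))
  list(input_dir = input_dir, output_dir = output_dir, cohorts = cohorts,
       pt2soc = pt2soc, ebgm_mode = ebgm_mode, role_codes = role_codes,
       q_cut = q_cut, lfc_cut = lfc_cut, make_plots = make_plots)
}

find_faers_files <- function(dir, kind) {
  list.files(dir, pattern = paste0("^", kind, ".*\\.(txt|TXT)$"),
             full.names = TRUE, ignore.case = TRUE)
}

#' Run the full pharmacovigilance pipeline
#'
#' Executes every stage in order on the FAERS files found in
#' `cfg$input_dir` and writes, per cohort, the PT-level signal table, the
#' sex-differential table, the SOC-level table and the time-to-onset
#' records and summary, plus cohort membership, a heatmap matrix, run
#' metadata (JSON with per-stage in/out counts) and figures.
#'
#' @param cfg A [run_config()] list.
#' @return Invisibly, a list with all result tibbles and the metadata.
#' @export
run_pipeline <- function(cfg) {
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(stages = list())
  note <- function(stage, ...) {
    meta$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  demo <- read_faers(find_faers_files(cfg$input_dir, "DEMO"), "DEMO")
  drug <- read_faers(find_faers_files(cfg$input_dir, "DRUG"), "DRUG")
  reac <- read_faers(find_faers_files(cfg$input_dir, "REAC"), "REAC")
  ther_files <- find_faers_files(cfg$input_dir, "THER")
  ther <- if (length(ther_files)) read_faers(ther_files, "THER") else NULL
  note("read", demo = nrow(demo), drug = nrow(drug), reac = nrow(reac),
       ther = if (is.null(ther)) 0L else nrow(ther),
       malformed = sum(attr(demo, "n_malformed"), attr(drug, "n_malformed"),
                       attr(reac, "n_malformed"),
                       if (!is.null(ther)) attr(ther, "n_malformed") else 0L))

  dedup <- deduplicate_reports(demo)
  note("deduplicate", versions_in = nrow(demo), cases_out = nrow(dedup))

  cases <- assemble_cases(dedup, drug, reac, ther)
  note("assemble", cases_with_ae = n_cases(cases),
       dropped_no_ae = nrow(dedup) - n_cases(cases))

  ch <- build_cohorts(cases, cfg$cohorts, role_codes = cfg$role_codes)
  do.call(note, c(list("cohorts"),
                  stats::setNames(lapply(ch$cohorts, length),
                                  names(ch$cohorts))))
  write_table(ch$membership, file.path(out_dir, "cohort_membership.csv"))

  map <- cfg$pt2soc
  if (is.character(map)) map <- read_pt2soc(map)
  if (is.null(map)) map <- tibble::tibble(pt = character(), soc = character())

  results <- list()
  soc_all <- list()
  tto_summaries <- list()
  for (nm in names(ch$cohorts)) {
    co <- ch$cohorts[[nm]]
    cm <- ch$comparators[[nm]]
    if (length(co) == 0L) {
      warning("cohort '", nm, "' has zero cases; emitting empty tables")
      empty <- tibble::tibble(pt = character())
      write_table(empty, file.path(out_dir, paste0(nm, "_signals.csv")))
      next
    }
    sig <- signal_metrics(build_tables(co, cm, cases), ebgm_mode = cfg$ebgm_mode)
    write_table(sig, file.path(out_dir, paste0(nm, "_signals.csv")))

    sx <- ror_ratio_test(sex_tables(co, cm, cases),
                         q_cut = cfg$q_cut, lfc_cut = cfg$lfc_cut)
    write_table(sx, file.path(out_dir, paste0(nm, "_sexdiff.csv")))

    soc <- soc_tables(co, cm, cases, map)
    soc$stratum <- nm
    write_table(soc, file.path(out_dir, paste0(nm, "_soc.csv")))
    soc_all[[nm]] <- soc

    tto <- compute_tto(subset_cases(cases, co))
    write_table(tto, file.path(out_dir, paste0(nm, "_tto_records.csv")))
    tto$cohort <- nm
    tto_summaries[[nm]] <- summarize_tto(tto, cohort = nm)

    results[[nm]] <- list(signals = sig, sexdiff = sx, soc = soc, tto = tto)
    note(paste0("signals_", nm), pts = nrow(sig),
         positive = sum(sig$positive),
         tto_included = sum(tto$status == "included"))
  }
  tto_summary <- dplyr::bind_rows(tto_summaries)
  write_table(tto_summary, file.path(out_dir, "tto_summary.csv"))
  if (length(soc_all)) {
    hm <- heatmap_matrix(dplyr::bind_rows(soc_all))
    hm_tb <- tibble::as_tibble(hm, rownames = "soc")
    write_table(hm_tb, file.path(out_dir, "soc_heatmap_matrix.csv"))
  }

  plots <- list()
  if (isTRUE(cfg$make_plots)) {
    for (nm in names(results)) {
      r <- results[[nm]]
      plots[[paste0(nm, "_volcano")]] <-
        save_plot(make_volcano(r$sexdiff, q_cut = cfg$q_cut,
                               lfc_cut = cfg$lfc_cut, title = nm),
                  file.path(out_dir, paste0(nm, "_volcano")))
      plots[[paste0(nm, "_forest")]] <-
        save_plot(make_forest(r$sexdiff, title = nm),
                  file.path(out_dir, paste0(nm, "_forest")))
    }
    if (length(soc_all)) {
      plots$soc_heatmap <- save_plot(
        make_heatmap(dplyr::bind_rows(soc_all)),
        file.path(out_dir, "soc_heatmap"))
    }
    all_tto <- dplyr::bind_rows(lapply(names(results), function(nm) {
      r <- results[[nm]]$tto
      r
    }))
    if (nrow(all_tto)) {
      plots$tto <- save_plot(make_tto_plot(all_tto),
                             file.path(out_dir, "tto"))
    }
  }

  meta$n_cases <- n_cases(cases)
  meta$cohort_sizes <- lapply(ch$cohorts, length)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cases = cases, cohorts = ch, results = results,
                 tto_summary = tto_summary, metadata = meta, plots = plots))
}

#' Restrict a `faers_cases` object to a set of caseids
#'
#' @param cases A `faers_cases` object.
#' @param ids Character vector of caseids to keep.
#' @return A `faers_cases` object containing only those cases.
#' @export
subset_cases <- function(cases, ids) {
  structure(list(
    demo   = cases$demo[cases$demo$caseid %in% ids, , drop = FALSE],
    pts    = cases$pts[cases$pts$caseid %in% ids, , drop = FALSE],
    drugs  = cases$drugs[cases$drugs$caseid %in% ids, , drop = FALSE],
    starts = cases$starts[cases$starts$caseid %in% ids, , drop = FALSE]),
    class = "faers_cases")
}
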