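#' Configuration for an end-to-end pipeline run
#'
#' A run takes quarterly files either from `input_dir` or freshly generated
#' from a [synth_config()], selects the query drug's cases, and produces a
#' ranked signal table. All randomness (synthetic generation only) flows
#' from the synth config's seed; given identical config and inputs, outputs
#' are byte-identical.
#'
#' @param query a [drug_query()].
#' @param input_dir directory of DEMO/DRUG/REAC quarterly files, or `NULL`.
#' @param synth a [synth_config()] used to generate the input, or `NULL`.
#'   Exactly one of `input_dir`/`synth` must be given.
#' @param pt_whitelist optional character vector of PTs restricting the
#'   signal table (e.g. a clinically chosen shortlist); matching is on
#'   normalized keys. The choice of such a shortlist is a human judgment and
#'   enters only here.
#' @param criteria a [signal_criteria()].
#' @param dedup `"latest"` or `"off"`, see [deduplicate_cases()].
#' @param dialect passed to the reader.
#' @param output_dir if non-`NULL`, CSV/report outputs are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(query, input_dir = NULL, synth = NULL,
                       pt_whitelist = NULL, criteria = signal_criteria(),
                       dedup = c("latest", "off"), dialect = "auto",
                       output_dir = NULL) {
  stopifnot(inherits(query, "drug_query"))
  if (is.null(input_dir) == is.null(synth)) {
    stop("give exactly one of input_dir or synth")
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  if (!is.null(criteria)) stopifnot(inherits(criteria, "signal_criteria"))
  structure(
    list(query = query, input_dir = input_dir, synth = synth,
         pt_whitelist = pt_whitelist, criteria = criteria,
         dedup = match.arg(dedup), dialect = dialect,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Stages: (optionally) generate synthetic quarters; parse every quarter;
#' deduplicate case versions; select the query drug's case ids under the
#' role filter; tally per-quarter event frequencies; compute the signal
#' table over the drug's PTs (or the whitelist). The run report records the
#' case funnel: report versions parsed, cases after deduplication,
#' collapsed versions, query-matched cases, and parse rejects.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `signal_table`,
#'   `frequency_table`, `cases` (the [deduplicate_cases()] result),
#'   `drug_case_ids`, `report` (stage counts), `paths` (written files, if
#'   `output_dir` was set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  input_dir <- config$input_dir
  if (!is.null(config$synth)) {
    input_dir <- file.path(config$output_dir %||% tempfile("faersignal"), "data")
    generate_dataset(config$synth, input_dir)
  }
  bundles <- read_quarter_dir(input_dir, dialect = config$dialect)
  cases <- deduplicate_cases(bundles, mode = config$dedup)
  drug_ids <- select_drug_cases(cases, config$query)
  if (length(drug_ids) == 0L) {
    stop(structure(
      class = c("faersignal_no_cases", "error", "condition"),
      list(message = paste0(
        "no case matches drug query \"", config$query$name,
        "\" under roles ", paste(config$query$roles, collapse = "/")),
        call = NULL)
    ))
  }
  freq <- tally_events(cases, drug_ids)
  pts <- NULL
  if (!is.null(config$pt_whitelist)) {
    keys <- normalize_pt(config$pt_whitelist)
    have <- unique(cases$case_events[case_id %in% drug_ids & pt_key %in% keys, pt])
    pts <- sort(have)
  }
  sig <- signal_table(cases, drug_ids, pts = pts, criteria = config$criteria)

  report <- list(
    quarters = names(bundles),
    dialects = vapply(bundles, `[[`, character(1), "dialect"),
    reports_parsed = cases$n_reports,
    cases_after_dedup = nrow(cases$cases),
    collapsed_versions = cases$n_collapsed,
    query_matched = length(drug_ids),
    pts_evaluated = nrow(sig),
    whitelist_applied = !is.null(config$pt_whitelist),
    rejected_rows = sum(vapply(bundles, function(b) {
      sum(vapply(b$rejects, function(r) r$n_rejected, integer(1)))
    }, integer(1))),
    orphan_reaction_keys = sum(vapply(bundles, function(b) {
      length(b$orphan_keys)
    }, integer(1)))
  )

  paths <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      signal_table = file.path(config$output_dir, "signal_table.csv"),
      frequency_table = file.path(config$output_dir, "frequency_table.csv"),
      run_report = file.path(config$output_dir, "run_report.txt"),
      rejects = file.path(config$output_dir, "rejects_report.txt")
    )
    write_signal_table(sig, paths[["signal_table"]])
    write_frequency_table(freq, paths[["frequency_table"]])
    write_run_report(report, paths[["run_report"]])
    write_rejects_report(bundles, paths[["rejects"]])
  }

  structure(
    list(signal_table = sig, frequency_table = freq, cases = cases,
         drug_case_ids = drug_ids, report = report, paths = paths),
    class = "pipeline_result"
  )
}

write_run_report <- function(report, path) {
  lines <- c(
    paste("quarters:", paste(report$quarters, collapse = " ")),
    paste("dialects:", paste(unique(report$dialects), collapse = " ")),
    paste("report versions parsed:", report$reports_parsed),
    paste("cases after deduplication:", report$cases_after_dedup),
    paste("collapsed versions:", report$collapsed_versions),
    paste("query-matched cases:", report$query_matched),
    paste("preferred terms evaluated:", report$pts_evaluated),
    paste("whitelist applied:", report$whitelist_applied),
    paste("rejected rows:", report$rejected_rows),
    paste("orphan reaction keys:", report$orphan_reaction_keys)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat("  ", r$reports_parsed, " report versions -> ", r$cases_after_dedup,
      " cases (", r$collapsed_versions, " collapsed), ",
      r$query_matched, " match the drug query\n", sep = "")
  cat("  signal table: ", nrow(x$signal_table), " PTs, ",
      sum(x$signal_table$overall), " overall-positive\n", sep = "")
  invisible(x)
}
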