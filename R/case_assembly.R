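#' Define the drug of interest
#'
#' A query names the drug and its synonyms (salts, brands, combination
#' labels), how verbatim drug-name strings are matched, and which reporter
#' role codes count: the default keeps primary and secondary suspects only,
#' the usual convention when screening for suspected causality, so a case
#' where the drug is merely concomitant is not attributed to it.
#'
#' @param name canonical drug name.
#' @param synonyms further names matched the same way.
#' @param match_mode `"substring"` (default; case-insensitive substring, so
#'   "LEVONORGESTREL TABLETS" matches "levonorgestrel") or `"exact"`.
#' @param roles subset of `c("PS", "SS", "C", "I")`; default `c("PS", "SS")`.
#' @return an object of class `drug_query`.
#' @export
drug_query <- function(name, synonyms = character(),
                       match_mode = c("substring", "exact"),
                       roles = c("PS", "SS")) {
  match_mode <- match.arg(match_mode)
  keys <- normalize_drug(c(name, synonyms))
  keys <- unique(keys[nzchar(keys)])
  if (!length(keys)) stop("drug_query needs at least one non-empty name")
  if (!all(roles %in% VALID_ROLES)) {
    stop("roles must be a subset of ", paste(VALID_ROLES, collapse = ", "))
  }
  structure(
    list(name = name, keys = keys, match_mode = match_mode,
         roles = unique(roles)),
    class = "drug_query"
  )
}

match_drug_keys <- function(drug_keys, query) {
  if (query$match_mode == "exact") {
    drug_keys %in% query$keys
  } else {
    Reduce(`|`, lapply(query$keys, function(k) {
      grepl(k, drug_keys, fixed = TRUE)
    }))
  }
}

#' Select the case ids reporting the drug of interest
#'
#' A case id is selected iff at least one of its drug rows matches the query
#' name set under the query's match mode *and* carries a role code in the
#' query's included roles. Works either on parsed quarter bundles (all
#' report versions are scanned) or on a deduplicated [case_set] (only each
#' case's latest version counts).
#'
#' @param x a `quarter_bundle`, a list of them, or a `case_set`.
#' @param query a [drug_query()].
#' @return sorted character vector of selected case ids.
#' @export
select_drug_cases <- function(x, query) {
  stopifnot(inherits(query, "drug_query"))
  rows <- if (inherits(x, "case_set")) {
    x$case_drugs
  } else {
    if (inherits(x, "quarter_bundle")) x <- list(x)
    data.table::rbindlist(lapply(x, function(b) {
      b$drug_rows[, .(case_id, drug_key, role_code)]
    }))
  }
  hit <- rows[match_drug_keys(drug_key, query) & role_code %in% query$roles]
  sort(unique(hit$case_id))
}

#' Deduplicate report versions into one record per case
#'
#' FAERS-style streams carry follow-up versions of the same case; standard
#' practice keeps only the latest version of each case id. `mode = "latest"`
#' keeps, per case id, the rows of the highest version number (ties broken
#' by the larger case key), taking drugs and events from that version only.
#' `mode = "off"` treats every report version as its own case.
#'
#' @param bundles a `quarter_bundle` or list of them.
#' @param mode `"latest"` (default) or `"off"`.
#' @return an object of class `case_set`: list with
#'   \describe{
#'     \item{cases}{data.table: `case_id`, `latest_key`, `version`,
#'       `quarter_first_seen`, `n_versions`}
#'     \item{case_drugs}{data.table of the latest version's drug mentions:
#'       `case_id`, `drug_name`, `drug_key`, `role_code`}
#'     \item{case_events}{data.table of distinct PTs per case: `case_id`,
#'       `pt`, `pt_key` (a PT counts once per case however many duplicate
#'       reaction rows exist)}
#'     \item{n_reports}{number of report versions seen}
#'     \item{n_collapsed}{versions collapsed away by deduplication}
#'   }
#' @export
deduplicate_cases <- function(bundles, mode = c("latest", "off")) {
  mode <- match.arg(mode)
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  stopifnot(all(vapply(bundles, inherits, logical(1), "quarter_bundle")))

  demo <- data.table::rbindlist(lapply(bundles, function(b) {
    d <- data.table::copy(b$demo_rows[, .(case_key, case_id, version)])
    d[, quarter := b$quarter %||% NA_character_]
    d
  }))
  drugs <- data.table::rbindlist(lapply(bundles, function(b) {
    b$drug_rows[, .(case_key, case_id, version, drug_name, drug_key, role_code)]
  }))
  reacs <- data.table::rbindlist(lapply(bundles, function(b) {
    b$reaction_rows[, .(case_key, case_id, version, pt, pt_key)]
  }))

  if (mode == "off") {
    demo[, case_id := case_key]
    drugs[, case_id := case_key]
    reacs[, case_id := case_key]
    demo[, version := 1L]
  }

  # latest version per case id; tie-break on the numerically larger key
  demo[, key_num := suppressWarnings(as.numeric(case_key))]
  data.table::setorder(demo, case_id, version, key_num, case_key, na.last = FALSE)
  cases <- demo[, .(
    latest_key = case_key[.N],
    version = version[.N],
    quarter_first_seen = if (all(is.na(quarter))) NA_character_ else
      min(quarter, na.rm = TRUE),
    n_versions = data.table::uniqueN(case_key)
  ), by = case_id]

  keep <- cases[, .(case_id, case_key = latest_key)]
  case_drugs <- unique(
    merge(drugs, keep, by = c("case_id", "case_key"))[,
      .(case_id, drug_name, drug_key, role_code)]
  )
  case_events <- unique(
    merge(reacs, keep, by = c("case_id", "case_key"))[, .(case_id, pt_key, pt)]
  )
  case_events <- case_events[, .(pt = pt[1L]), by = .(case_id, pt_key)]

  structure(
    list(
      cases = cases,
      case_drugs = case_drugs,
      case_events = case_events,
      n_reports = data.table::uniqueN(demo$case_key),
      n_collapsed = data.table::uniqueN(demo$case_key) - nrow(cases)
    ),
    class = "case_set"
  )
}

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set> ", nrow(x$cases), " cases (", x$n_reports, " report versions, ",
      x$n_collapsed, " collapsed)\n", sep = "")
  invisible(x)
}

#' Tally per-quarter event frequencies among selected cases
#'
#' Counts, for every preferred term occurring in the selected cases, the
#' number of distinct cases reporting it per quarter and overall. The
#' counting unit is the case: a PT repeated in a case's reaction rows
#' contributes one. Quarters with no occurrence of a PT are present as
#' explicit zeros; the quarter of a case is the quarter it was first seen.
#'
#' @param cases a [deduplicate_cases()] result.
#' @param case_ids case ids to tally (e.g. from [select_drug_cases()]).
#' @return an object of class `frequency_table`: data.table with columns
#'   `pt`, `pt_key`, `quarter`, `count`, `total`, ordered alphabetically by
#'   PT then quarter; attribute `n_orphans` counts selected cases with no
#'   reaction row at all.
#' @export
tally_events <- function(cases, case_ids) {
  stopifnot(inherits(cases, "case_set"))
  sel <- cases$cases[case_id %in% case_ids]
  ev <- merge(cases$case_events[case_id %in% case_ids],
              sel[, .(case_id, quarter = quarter_first_seen)],
              by = "case_id")
  n_orphans <- length(setdiff(case_ids, unique(cases$case_events$case_id)))
  quarters <- sort(unique(sel$quarter_first_seen))
  if (nrow(ev) == 0L) {
    out <- data.table::data.table(
      pt = character(), pt_key = character(), quarter = character(),
      count = integer(), total = integer()
    )
  } else {
    counts <- ev[, .(count = data.table::uniqueN(case_id)),
                 by = .(pt_key, quarter)]
    pt_names <- ev[, .(pt = pt[1L]), by = pt_key]
    grid <- data.table::CJ(pt_key = unique(counts$pt_key),
                           quarter = quarters, unique = TRUE)
    grid <- merge(grid, pt_names, by = "pt_key")
    out <- merge(grid, counts[, .(pt_key, quarter, count)],
                 by = c("pt_key", "quarter"), all.x = TRUE)
    out[is.na(count), count := 0L]
    out[, total := sum(count), by = pt_key]
    data.table::setcolorder(out, c("pt", "pt_key", "quarter", "count", "total"))
    data.table::setorder(out, pt, quarter)
  }
  data.table::setattr(out, "n_orphans", n_orphans)
  data.table::setattr(out, "class", c("frequency_table", class(out)))
  out[]
}

#' Write a frequency table as CSV
#'
#' Columns `pt`, `quarter`, `count`, `total`; rows ordered alphabetically by
#' PT then quarter, so output is deterministic.
#'
#' @param x a [tally_events()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_frequency_table <- function(x, path) {
  out <- as.data.frame(x)[, c("pt", "quarter", "count", "total")]
  out <- out[order(out$pt, out$quarter), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
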