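# Column mappings per file dialect. The reporting system changed format at
# 2012Q4: before, all three files are keyed by ISR (one id per report
# version, the stable case id lives in DEMO's CASE column); after, files
# carry primaryid (report version key) and caseid (stable case id), with
# caseversion in DEMO. Mappings live here as data, not scattered in code.
DIALECTS <- list(
  legacy = list(
    marker = "ISR",
    demo = c(case_key = "ISR", case_id = "CASE", age = "AGE", sex = "GNDR_COD"),
    drug = c(case_key = "ISR", drug_name = "DRUGNAME", role_code = "ROLE_COD"),
    reac = c(case_key = "ISR", pt = "PT")
  ),
  modern = list(
    marker = "primaryid",
    demo = c(case_key = "primaryid", case_id = "caseid", version = "caseversion",
             age = "age", sex = "sex"),
    drug = c(case_key = "primaryid", case_id = "caseid",
             drug_name = "drugname", role_code = "role_cod"),
    reac = c(case_key = "primaryid", case_id = "caseid", pt = "pt")
  )
)

VALID_ROLES <- c("PS", "SS", "C", "I")

# Parse one "$"-delimited file into a data.table. Rows whose field count
# disagrees with the header are collected in a rejects record, never dropped
# silently. Files are read as UTF-8; lines that are not valid UTF-8 fall
# back to latin-1 and are counted.
parse_dollar_file <- function(path, max_reject_lines = 5L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !nzchar(lines[1])) {
    stop("empty file: ", path)
  }
  bad_enc <- !validUTF8(lines)
  if (any(bad_enc)) {
    lines[bad_enc] <- iconv(lines[bad_enc], from = "latin1", to = "UTF-8")
  }
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  nc <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  ok <- lengths(parts) == nc
  tab <- if (any(ok)) {
    m <- matrix(unlist(parts[ok], use.names = FALSE), ncol = nc, byrow = TRUE)
    dt <- data.table::as.data.table(m)
    data.table::setnames(dt, header)
    dt
  } else {
    dt <- data.table::as.data.table(
      stats::setNames(replicate(nc, character(0), simplify = FALSE), header)
    )
    dt
  }
  list(
    table = tab,
    header = header,
    rejects = list(
      file = basename(path),
      n_rows = length(body),
      n_rejected = sum(!ok),
      rejected_lines = utils::head(body[!ok], max_reject_lines),
      n_encoding_fallback = sum(bad_enc)
    )
  )
}

detect_dialect <- function(header) {
  for (d in names(DIALECTS)) {
    if (DIALECTS[[d]]$marker %in% header) return(d)
  }
  stop(
    "cannot detect file dialect: header has neither \"ISR\" (legacy) nor ",
    "\"primaryid\" (modern); saw: ", paste(header, collapse = ", ")
  )
}

# map raw columns to the normalized names, erroring on missing mandatory ones
map_columns <- function(parsed, mapping, dialect, what) {
  missing <- setdiff(unname(mapping), parsed$header)
  if (length(missing)) {
    stop("missing mandatory column(s) ", paste(missing, collapse = ", "),
         " in ", what, " file under the ", dialect, " dialect")
  }
  dt <- parsed$table[, unname(mapping), with = FALSE]
  data.table::setnames(dt, names(mapping))
  dt
}

#' Read one quarter's DEMO/DRUG/REAC files into a normalized bundle
#'
#' Parses the three "$"-delimited quarterly files, auto-detecting the dialect
#' from the header if requested (`ISR` column = legacy, `primaryid` =
#' modern), and normalizes them to one record model: every row carries an
#' opaque per-version `case_key`, the stable `case_id`, and a `version`
#' number (the `caseversion` column in the modern dialect; the rank of the
#' ISR within its case in the legacy dialect, where a follow-up report is a
#' new ISR for the same CASE). Malformed rows land in a per-file rejects
#' record; reaction rows whose case key never occurs in the drug file are
#' kept but reported as orphans.
#'
#' @param demo,drug,reac paths to the three files.
#' @param dialect `"auto"` (default), `"legacy"` or `"modern"`.
#' @param quarter optional quarter label attached to the bundle.
#' @return an object of class `quarter_bundle`: a list with `quarter`,
#'   `dialect`, `demo_rows`, `drug_rows`, `reaction_rows` (data.tables),
#'   `rejects` (per-file parse report), `orphan_keys`, and
#'   `n_unknown_roles` (drug rows whose role code is outside PS/SS/C/I,
#'   preserved verbatim but flagged).
#' @export
read_quarter <- function(demo, drug, reac, dialect = c("auto", "legacy", "modern"),
                         quarter = NULL) {
  dialect <- match.arg(dialect)
  p_demo <- parse_dollar_file(demo)
  p_drug <- parse_dollar_file(drug)
  p_reac <- parse_dollar_file(reac)
  if (dialect == "auto") dialect <- detect_dialect(p_demo$header)
  spec <- DIALECTS[[dialect]]

  demo_rows <- map_columns(p_demo, spec$demo, dialect, "DEMO")
  drug_rows <- map_columns(p_drug, spec$drug, dialect, "DRUG")
  reac_rows <- map_columns(p_reac, spec$reac, dialect, "REAC")

  if (dialect == "legacy") {
    # stable case id comes from DEMO; version = rank of ISR within the case
    demo_rows[, version := frank(as.numeric(case_key), ties.method = "dense"),
              by = case_id]
    key_map <- demo_rows[, .(case_key, case_id, version)]
  } else {
    demo_rows[, version := as.integer(version)]
    key_map <- demo_rows[, .(case_key, version)]
  }

  # DRUG/REAC rows get case_id (legacy) and version through DEMO; keys
  # absent from DEMO fall back to the key itself at version 1
  join_keys <- function(dt) {
    dt <- merge(dt, key_map, by = "case_key", all.x = TRUE, sort = FALSE)
    dt[is.na(version), version := 1L]
    if (dialect == "legacy") dt[is.na(case_id), case_id := case_key]
    dt
  }
  drug_rows <- join_keys(drug_rows)
  reac_rows <- join_keys(reac_rows)

  drug_rows[, role_code := toupper(squish_ws(role_code))]
  n_unknown_roles <- drug_rows[!role_code %in% VALID_ROLES, .N]
  drug_rows[, drug_key := normalize_drug(drug_name)]

  reac_rows[, pt := squish_ws(pt)]
  invalid_pt <- !nzchar(reac_rows$pt)
  n_invalid_pt <- sum(invalid_pt)
  if (n_invalid_pt) reac_rows <- reac_rows[!invalid_pt]
  reac_rows[, pt_key := tolower(pt)]

  orphan_keys <- setdiff(reac_rows$case_key, drug_rows$case_key)

  structure(
    list(
      quarter = quarter,
      dialect = dialect,
      demo_rows = demo_rows,
      drug_rows = drug_rows,
      reaction_rows = reac_rows,
      rejects = list(demo = p_demo$rejects, drug = p_drug$rejects,
                     reac = p_reac$rejects),
      orphan_keys = orphan_keys,
      n_unknown_roles = n_unknown_roles,
      n_invalid_pt = n_invalid_pt
    ),
    class = "quarter_bundle"
  )
}

#' Read every quarter found in a directory
#'
#' Looks for `DEMOyyQq` / `DRUGyyQq` / `REACyyQq` file triples (any
#' extension) under `dir` and reads each with [read_quarter()]. Two-digit
#' years are mapped to 20yy.
#'
#' @param dir directory holding quarterly files.
#' @param dialect passed to [read_quarter()].
#' @return a named list of `quarter_bundle`s, sorted by quarter label.
#' @export
read_quarter_dir <- function(dir, dialect = "auto") {
  demo_files <- list.files(dir, pattern = "^DEMO[0-9]{2}Q[1-4]", full.names = TRUE)
  if (!length(demo_files)) stop("no DEMOyyQq files found under ", dir)
  stems <- sub("^DEMO([0-9]{2}Q[1-4]).*$", "\\1", basename(demo_files))
  stems <- sort(unique(stems))
  bundles <- lapply(stems, function(s) {
    find1 <- function(prefix) {
      f <- list.files(dir, pattern = paste0("^", prefix, s), full.names = TRUE)
      if (length(f) != 1L) {
        stop("expected exactly one ", prefix, s, " file under ", dir,
             "; found ", length(f))
      }
      f
    }
    q <- paste0("20", substr(s, 1, 2), "Q", substr(s, 4, 4))
    read_quarter(find1("DEMO"), find1("DRUG"), find1("REAC"),
                 dialect = dialect, quarter = q)
  })
  names(bundles) <- paste0("20", substr(stems, 1, 2), "Q", substr(stems, 4, 4))
  bundles
}

#' Write a plain-text parse/rejects report for one or more bundles
#'
#' @param bundles a `quarter_bundle` or list of them.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_rejects_report <- function(bundles, path) {
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  lines <- character(0)
  for (b in bundles) {
    lines <- c(lines, sprintf("quarter %s (dialect %s)",
                              b$quarter %||% "?", b$dialect))
    for (r in b$rejects) {
      lines <- c(lines, sprintf(
        "  %s: %d rows, %d rejected, %d encoding fallback(s)",
        r$file, r$n_rows, r$n_rejected, r$n_encoding_fallback
      ))
      if (length(r$rejected_lines)) {
        lines <- c(lines, paste0("    | ", r$rejected_lines))
      }
    }
    lines <- c(lines, sprintf(
      "  orphan reaction keys: %d; unknown role codes: %d; invalid PTs: %d",
      length(b$orphan_keys), b$n_unknown_roles, b$n_invalid_pt
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat("<quarter_bundle ", x$quarter %||% "?", ", dialect ", x$dialect, ">\n",
      sep = "")
  cat("  demo:", nrow(x$demo_rows), " drug:", nrow(x$drug_rows),
      " reac:", nrow(x$reaction_rows), "rows\n")
  rej <- sum(vapply(x$rejects, function(r) r$n_rejected, integer(1)))
  cat("  rejected rows:", rej, " orphan keys:", length(x$orphan_keys), "\n")
  invisible(x)
}
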