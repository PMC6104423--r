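#' Build a drug--event 2x2 contingency table
#'
#' The table is defined over distinct deduplicated cases: `n_ij` cases with
#' both the drug and the event, `n_i` cases with the event (any drug),
#' `n_j` cases with the drug (any event), `n` total cases. The derived cells
#' are `a = n_ij`, `b = n_j - n_ij` (drug without event), `c = n_i - n_ij`
#' (event without drug), `d = n - n_i - n_j + n_ij`.
#'
#' @param n_ij,n_i,n_j,n the four counts.
#' @return an object of class `contingency_table` with fields
#'   `n_ij`, `n_i`, `n_j`, `n`, `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' contingency_table(n_ij = 20, n_i = 120, n_j = 100, n = 10000)
contingency_table <- function(n_ij, n_i, n_j, n) {
  stopifnot(
    length(n_ij) == 1, length(n_i) == 1, length(n_j) == 1, length(n) == 1,
    is.finite(n_ij), is.finite(n_i), is.finite(n_j), is.finite(n)
  )
  if (n < 1) stop("total case count n must be >= 1")
  a <- n_ij
  b <- n_j - n_ij
  c <- n_i - n_ij
  d <- n - n_i - n_j + n_ij
  if (min(a, b, c, d) < 0) {
    stop(sprintf(
      "inconsistent counts (n_ij=%g, n_i=%g, n_j=%g, n=%g): cell(s) negative",
      n_ij, n_i, n_j, n
    ))
  }
  structure(
    list(n_ij = a, n_i = n_i, n_j = n_j, n = n, a = a, b = b, c = c, d = d),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the contingency table for one preferred term
#'
#' Counts distinct cases in a deduplicated [case_set]: the drug margin is
#' the supplied set of query-drug case ids, the event margin all cases whose
#' events contain the PT.
#'
#' @param pt preferred-term string (normalized internally).
#' @param drug_case_ids case ids attributed to the drug of interest.
#' @param cases a [deduplicate_cases()] result covering all cases.
#' @return a [contingency_table()].
#' @export
build_table <- function(pt, drug_case_ids, cases) {
  stopifnot(inherits(cases, "case_set"))
  key <- normalize_pt(pt)
  event_ids <- unique(cases$case_events[pt_key == key, case_id])
  all_ids <- cases$cases$case_id
  drug_ids <- unique(drug_case_ids[drug_case_ids %in% all_ids])
  contingency_table(
    n_ij = length(intersect(drug_ids, event_ids)),
    n_i = length(event_ids),
    n_j = length(drug_ids),
    n = nrow(cases$cases)
  )
}

# shared continuity handling: add 0.5 to every cell only if some cell is 0.
# returns NULL when the table stays degenerate with correction disabled.
corrected_cells <- function(t, continuity) {
  cells <- c(a = t$a, b = t$b, c = t$c, d = t$d)
  if (min(cells) > 0) return(list(cells = cells, applied = FALSE))
  if (!continuity) return(NULL)
  list(cells = cells + 0.5, applied = TRUE)
}

undefined_estimate <- function(reason, extra = list()) {
  c(list(estimate = NA_real_, low = NA_real_, high = NA_real_,
         se_log = NA_real_, correction_applied = FALSE,
         defined = FALSE, reason = reason), extra)
}

#' Reporting odds ratio with 95% confidence bounds
#'
#' `ROR = (a d)/(b c)`; `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`; bounds
#' `exp(ln ROR +/- 1.96 SE)`. If any cell is zero a continuity correction of
#' 0.5 is added to all four cells (flagged in the result); with
#' `continuity = FALSE` such tables yield an explicitly undefined result,
#' never a silent zero.
#'
#' @param t a [contingency_table()].
#' @param continuity apply the +0.5 correction when a cell is zero.
#' @return list with `estimate`, `low`, `high`, `se_log`,
#'   `correction_applied`, `defined` (logical), and `reason` when undefined.
#' @export
#' @examples
#' t <- contingency_table(20, 120, 100, 10000)
#' compute_ror(t)
compute_ror <- function(t, continuity = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  cc <- corrected_cells(t, continuity)
  if (is.null(cc)) {
    return(undefined_estimate(
      "zero cell with continuity correction disabled"))
  }
  a <- cc$cells[["a"]]; b <- cc$cells[["b"]]
  c <- cc$cells[["c"]]; d <- cc$cells[["d"]]
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    estimate = est,
    low = exp(log(est) - 1.96 * se),
    high = exp(log(est) + 1.96 * se),
    se_log = se,
    correction_applied = cc$applied,
    defined = TRUE,
    reason = NA_character_
  )
}

#' Proportional reporting ratio with 95% confidence bounds
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`;
#' `SE(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`; bounds
#' `exp(ln PRR +/- 1.96 SE)`. Continuity handling as in [compute_ror()].
#'
#' @inheritParams compute_ror
#' @return same shape as [compute_ror()].
#' @export
compute_prr <- function(t, continuity = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  cc <- corrected_cells(t, continuity)
  if (is.null(cc)) {
    return(undefined_estimate(
      "zero cell with continuity correction disabled"))
  }
  a <- cc$cells[["a"]]; b <- cc$cells[["b"]]
  c <- cc$cells[["c"]]; d <- cc$cells[["d"]]
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(
    estimate = est,
    low = exp(log(est) - 1.96 * se),
    high = exp(log(est) + 1.96 * se),
    se_log = se,
    correction_applied = cc$applied,
    defined = TRUE,
    reason = NA_character_
  )
}

#' Chi-squared statistic of the 2x2 table
#'
#' By default the Yates continuity-corrected statistic
#' `n (|ad - bc| - n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, with the corrected
#' difference floored at zero (the classic form used alongside the
#' PRR >= 2, chi-squared >= 4, n >= 3 screening criterion); set
#' `correct = FALSE` for the uncorrected Pearson statistic.
#'
#' @param t a [contingency_table()].
#' @param correct apply the Yates correction (default `TRUE`).
#' @return list with `statistic`, `defined`, `reason`.
#' @export
compute_chi2 <- function(t, correct = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(list(statistic = NA_real_, defined = FALSE,
                reason = "zero margin: chi-squared undefined"))
  }
  diff <- abs(a * d - b * c)
  if (correct) diff <- max(0, diff - n / 2)
  stat <- n * diff^2 / prod(margins)
  list(statistic = stat, defined = TRUE, reason = NA_character_)
}

#' Information component with lower credibility bound
#'
#' The default is the shrinkage form
#' `IC = log2((n_ij + 0.5) / (E + 0.5))` with expected count
#' `E = n_i n_j / n`, a stabilized observed/expected measure that is finite
#' at `n_ij = 0` and shrinks small counts toward no association. Its
#' standard deviation uses the delta-method approximation
#' `SD = 1 / (ln 2 * sqrt(n_ij + 0.5))`, and the signal bound is
#' `ic_low = IC - 2 SD`. With `shrink = FALSE` the plain
#' `log2(n_ij n / (n_i n_j))` is returned (undefined at `n_ij = 0`), with
#' `SD = 1 / (ln 2 * sqrt(n_ij))`.
#'
#' @param t a [contingency_table()].
#' @param shrink use the shrinkage form (default `TRUE`).
#' @return list with `ic`, `ic_low`, `sd`, `defined`, `reason`.
#' @export
compute_ic <- function(t, shrink = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n_i == 0 || t$n_j == 0) {
    return(list(ic = NA_real_, ic_low = NA_real_, sd = NA_real_,
                defined = FALSE, reason = "zero margin: IC undefined"))
  }
  e <- t$n_i * t$n_j / t$n
  if (shrink) {
    ic <- log2((t$n_ij + 0.5) / (e + 0.5))
    sd <- 1 / (log(2) * sqrt(t$n_ij + 0.5))
  } else {
    if (t$n_ij == 0) {
      return(list(ic = NA_real_, ic_low = NA_real_, sd = NA_real_,
                  defined = FALSE,
                  reason = "n_ij = 0: unshrunk IC undefined"))
    }
    ic <- log2(t$n_ij / e)
    sd <- 1 / (log(2) * sqrt(t$n_ij))
  }
  list(ic = ic, ic_low = ic - 2 * sd, sd = sd, defined = TRUE,
       reason = NA_character_)
}

#' All disproportionality metrics for one table
#'
#' @param t a [contingency_table()].
#' @param continuity passed to [compute_ror()]/[compute_prr()].
#' @param yates use the Yates-corrected chi-squared (default `TRUE`).
#' @param shrink use the shrinkage IC (default `TRUE`).
#' @return an object of class `signal_metrics`: one-row data.frame with
#'   `n_ij`, `n_i`, `n_j`, `n`, `ror`, `ror_low`, `ror_high`, `prr`,
#'   `prr_low`, `prr_high`, `chi2`, `ic`, `ic_low`, `correction_applied`.
#'   Undefined statistics appear as `NA`.
#' @export
signal_metrics <- function(t, continuity = TRUE, yates = TRUE, shrink = TRUE) {
  ror <- compute_ror(t, continuity = continuity)
  prr <- compute_prr(t, continuity = continuity)
  chi <- compute_chi2(t, correct = yates)
  ic <- compute_ic(t, shrink = shrink)
  out <- data.frame(
    n_ij = t$n_ij, n_i = t$n_i, n_j = t$n_j, n = t$n,
    ror = ror$estimate, ror_low = ror$low, ror_high = ror$high,
    prr = prr$estimate, prr_low = prr$low, prr_high = prr$high,
    chi2 = chi$statistic,
    ic = ic$ic, ic_low = ic$ic_low,
    correction_applied = isTRUE(ror$correction_applied)
  )
  class(out) <- c("signal_metrics", "data.frame")
  out
}

#' Signal criteria thresholds
#'
#' The screening rule requires all three of: (i) `PRR >= prr_threshold`
#' together with chi-squared `>= chi2_threshold` and at least `min_reports`
#' cases of the pair; (ii) `IC - 2 SD > 0`; (iii) `ROR - 1.96 SE > 1`, i.e.
#' the ROR 95% CI lower bound above 1. Both interval rules are strict
#' inequalities.
#'
#' @param prr_threshold default 2.0.
#' @param chi2_threshold default 4.0.
#' @param min_reports default 3.
#' @return an object of class `signal_criteria`.
#' @export
signal_criteria <- function(prr_threshold = 2.0, chi2_threshold = 4.0,
                            min_reports = 3L) {
  stopifnot(prr_threshold > 0, chi2_threshold > 0, min_reports > 0)
  structure(
    list(prr_threshold = prr_threshold, chi2_threshold = chi2_threshold,
         min_reports = as.integer(min_reports)),
    class = "signal_criteria"
  )
}

#' Classify one pair's metrics against the signal criteria
#'
#' An undefined (NA) statistic fails its criterion, with the reason kept.
#'
#' @param metrics a [signal_metrics()] row.
#' @param criteria a [signal_criteria()].
#' @return an object of class `signal_decision`: list with the three
#'   per-criterion booleans `prr_chi2_n`, `ic_positive`, `ror_positive`,
#'   their conjunction `overall`, and `reasons` for failed criteria.
#' @export
classify_signal <- function(metrics, criteria = signal_criteria()) {
  stopifnot(inherits(metrics, "signal_metrics"),
            inherits(criteria, "signal_criteria"))
  ok <- function(x) !is.na(x)
  reasons <- character(0)

  prr_chi2_n <- ok(metrics$prr) && ok(metrics$chi2) &&
    metrics$prr >= criteria$prr_threshold &&
    metrics$chi2 >= criteria$chi2_threshold &&
    metrics$n_ij >= criteria$min_reports
  if (!prr_chi2_n) {
    reasons <- c(reasons, if (!ok(metrics$prr) || !ok(metrics$chi2)) {
      "PRR or chi-squared undefined"
    } else {
      sprintf("PRR %.3g / chi2 %.3g / n %d below thresholds",
              metrics$prr, metrics$chi2, metrics$n_ij)
    })
  }
  ic_positive <- ok(metrics$ic_low) && metrics$ic_low > 0
  if (!ic_positive) reasons <- c(reasons, "IC - 2SD not above 0")
  ror_positive <- ok(metrics$ror_low) && metrics$ror_low > 1
  if (!ror_positive) reasons <- c(reasons, "ROR CI lower bound not above 1")

  structure(
    list(
      prr_chi2_n = prr_chi2_n,
      ic_positive = ic_positive,
      ror_positive = ror_positive,
      overall = prr_chi2_n && ic_positive && ror_positive,
      reasons = reasons
    ),
    class = "signal_decision"
  )
}

#' @export
print.signal_decision <- function(x, ...) {
  cat("<signal_decision> overall:", x$overall,
      "| prr_chi2_n:", x$prr_chi2_n,
      "ic_positive:", x$ic_positive,
      "ror_positive:", x$ror_positive, "\n")
  invisible(x)
}

#' Signal table over many preferred terms
#'
#' Builds the contingency table, metrics and decision for each PT and
#' returns one ranked table, sorted by `n_ij` descending with alphabetical
#' PT tie-break (the most-reported pairs first).
#'
#' @param cases a [deduplicate_cases()] result.
#' @param drug_case_ids case ids of the drug of interest.
#' @param pts character vector of PTs to evaluate; default: every PT
#'   occurring among the drug's cases.
#' @param criteria a [signal_criteria()].
#' @param ... passed to [signal_metrics()].
#' @return data.frame (class `signal_table`) with columns `pt`, the counts,
#'   all metrics, the three per-criterion flags and `overall`.
#' @export
signal_table <- function(cases, drug_case_ids, pts = NULL,
                         criteria = signal_criteria(), ...) {
  stopifnot(inherits(cases, "case_set"))
  if (is.null(pts)) {
    drug_ev <- cases$case_events[case_id %in% drug_case_ids]
    pts <- sort(unique(drug_ev$pt))
  }
  if (!length(pts)) stop("no preferred terms to evaluate")
  rows <- lapply(pts, function(p) {
    t <- build_table(p, drug_case_ids, cases)
    m <- signal_metrics(t, ...)
    d <- classify_signal(m, criteria)
    cbind(
      data.frame(pt = squish_ws(p)), as.data.frame(m),
      data.frame(prr_chi2_n = d$prr_chi2_n, ic_positive = d$ic_positive,
                 ror_positive = d$ror_positive, overall = d$overall)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_ij, out$pt), ]
  rownames(out) <- NULL
  class(out) <- c("signal_table", "data.frame")
  out
}

#' Write a signal table as CSV
#'
#' Fixed column order; floating-point columns rounded to 6 significant
#' digits so reruns are byte-identical.
#'
#' @param x a [signal_table()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_signal_table <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
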