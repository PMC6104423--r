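#' Configuration for the synthetic quarterly report generator
#'
#' Defines a generative model for FAERS-like quarterly report streams with
#' analytically known drug--event association strengths. Per case, each drug
#' in the vocabulary is an independent Bernoulli draw with its marginal
#' probability; each event is Bernoulli with its marginal probability,
#' multiplied by `rate_ratio` for every planted association whose drug is
#' present in the case (so `rate_ratio` is the true reporting-rate ratio
#' of the pair, and `rate_ratio = 1` means exact independence). A
#' `duplicate_fraction` of cases is emitted twice under one case id with
#' consecutive version numbers and a perturbed age, so downstream
#' deduplication is observable.
#'
#' Configurations in which `rate_ratio * p_event` would exceed 1 for any
#' planted pair are rejected at construction: the conditional event
#' probability would have to be clamped and the closed-form expectations in
#' [expected_counts()] would no longer describe the generator.
#'
#' @param n_cases_per_quarter positive integer, distinct cases per quarter.
#' @param quarters character vector of quarter labels `"YYYYQn"`, ordered.
#' @param drug_vocabulary named numeric vector: names are drug names, values
#'   their per-case marginal report probabilities in `[0, 1]`. Each drug is
#'   an independent Bernoulli, not a category of a simplex.
#' @param event_vocabulary named numeric vector of MedDRA preferred terms and
#'   their marginal probabilities, same convention.
#' @param planted_associations `NULL` or a data.frame with columns `drug`,
#'   `event`, `rate_ratio` (`>= 0`); drug/event must be in the vocabularies.
#' @param duplicate_fraction proportion in `[0, 1)` of cases emitted as two
#'   versions of one case id.
#' @param suspect_role_distribution named probabilities over role codes
#'   `PS`, `SS`, `C`, `I` used to label each drug mention; must sum to 1.
#' @param seed integer master seed; identical seed and config give
#'   byte-identical output files.
#' @return an object of class `synth_config`.
#' @seealso [generate_quarter()], [generate_dataset()], [expected_counts()]
#' @export
#' @examples
#' cfg <- synth_config(
#'   n_cases_per_quarter = 500,
#'   quarters = c("2012Q3", "2012Q4"),
#'   drug_vocabulary = c(levonorgestrel = 0.05, ibuprofen = 0.2),
#'   event_vocabulary = c("Menstruation delayed" = 0.02, "Headache" = 0.1),
#'   planted_associations = data.frame(
#'     drug = "levonorgestrel", event = "Menstruation delayed", rate_ratio = 6
#'   ),
#'   seed = 42
#' )
synth_config <- function(n_cases_per_quarter,
                         quarters,
                         drug_vocabulary,
                         event_vocabulary,
                         planted_associations = NULL,
                         duplicate_fraction = 0,
                         suspect_role_distribution = c(PS = 0.6, SS = 0.25, C = 0.15),
                         seed = 1L) {
  stopifnot(
    is.numeric(n_cases_per_quarter), length(n_cases_per_quarter) == 1L,
    n_cases_per_quarter >= 1, n_cases_per_quarter == floor(n_cases_per_quarter)
  )
  if (length(quarters) < 1L || any(!is_quarter_label(quarters))) {
    stop("quarters must all match the \"YYYYQn\" pattern (e.g. \"2012Q3\"); got: ",
         paste(quarters[!is_quarter_label(quarters)], collapse = ", "))
  }
  if (anyDuplicated(quarters)) stop("duplicated quarter labels")
  check_vocab <- function(v, what) {
    if (is.null(names(v)) || any(!nzchar(names(v))) || !is.numeric(v)) {
      stop(what, " must be a named numeric vector (name = item, value = probability)")
    }
    if (any(v < 0 | v > 1)) stop(what, " probabilities must lie in [0, 1]")
    if (anyDuplicated(normalize_drug(names(v)))) stop("duplicated names in ", what)
    v
  }
  drug_vocabulary <- check_vocab(drug_vocabulary, "drug_vocabulary")
  event_vocabulary <- check_vocab(event_vocabulary, "event_vocabulary")

  if (is.null(planted_associations)) {
    planted_associations <- data.frame(
      drug = character(), event = character(), rate_ratio = numeric()
    )
  }
  pa <- as.data.frame(planted_associations, stringsAsFactors = FALSE)
  if (!all(c("drug", "event", "rate_ratio") %in% names(pa))) {
    stop("planted_associations needs columns drug, event, rate_ratio")
  }
  if (nrow(pa)) {
    miss_d <- setdiff(pa$drug, names(drug_vocabulary))
    miss_e <- setdiff(pa$event, names(event_vocabulary))
    if (length(miss_d)) stop("planted drug(s) not in vocabulary: ", paste(miss_d, collapse = ", "))
    if (length(miss_e)) stop("planted event(s) not in vocabulary: ", paste(miss_e, collapse = ", "))
    if (any(!is.finite(pa$rate_ratio)) || any(pa$rate_ratio < 0)) {
      stop("rate_ratio must be finite and >= 0")
    }
    cond <- pa$rate_ratio * event_vocabulary[pa$event]
    if (any(cond > 1 + 1e-12)) {
      bad <- which(cond > 1 + 1e-12)[1L]
      stop(sprintf(
        "planted association (%s, %s, rate_ratio=%g) gives conditional event probability %.3f > 1",
        pa$drug[bad], pa$event[bad], pa$rate_ratio[bad], cond[bad]
      ))
    }
    if (anyDuplicated(pa[c("drug", "event")])) stop("duplicated planted (drug, event) pair")
  }

  stopifnot(
    is.numeric(duplicate_fraction), length(duplicate_fraction) == 1L,
    duplicate_fraction >= 0, duplicate_fraction < 1
  )
  rd <- suspect_role_distribution
  if (is.null(names(rd)) || !all(names(rd) %in% c("PS", "SS", "C", "I"))) {
    stop("suspect_role_distribution must be named with codes among PS, SS, C, I")
  }
  if (any(rd < 0) || abs(sum(rd) - 1) > 1e-8) {
    stop("suspect_role_distribution must be non-negative and sum to 1")
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed %% .Machine$integer.max)

  structure(
    list(
      n_cases_per_quarter = as.integer(n_cases_per_quarter),
      quarters = as.character(quarters),
      drug_vocabulary = drug_vocabulary,
      event_vocabulary = event_vocabulary,
      planted_associations = pa,
      duplicate_fraction = duplicate_fraction,
      suspect_role_distribution = rd,
      seed = seed
    ),
    class = "synth_config"
  )
}

# deterministic per-quarter seed stream derived from the master seed
quarter_seed <- function(config, idx) {
  as.integer((as.double(config$seed) * 1009 + idx * 7919) %% 2147483647)
}

# simulate the latent case structure of one quarter: which drugs and events
# each case carries, drug roles, and demographics. Filler rows guarantee every
# case has >= 1 drug and >= 1 reaction without touching vocabulary marginals.
simulate_cases <- function(config, quarter) {
  idx <- match(quarter, config$quarters)
  set.seed(quarter_seed(config, idx))
  n <- config$n_cases_per_quarter
  dv <- config$drug_vocabulary
  ev <- config$event_vocabulary
  pa <- config$planted_associations

  drug_mat <- vapply(dv, function(p) stats::rbinom(n, 1L, p), integer(n))
  drug_mat <- matrix(drug_mat, nrow = n, dimnames = list(NULL, names(dv)))

  event_mat <- matrix(0L, n, length(ev), dimnames = list(NULL, names(ev)))
  for (e in names(ev)) {
    prob <- rep(ev[[e]], n)
    rows <- pa[pa$event == e, , drop = FALSE]
    if (nrow(rows)) {
      for (k in seq_len(nrow(rows))) {
        present <- drug_mat[, rows$drug[k]] == 1L
        prob[present] <- prob[present] * rows$rate_ratio[k]
      }
    }
    event_mat[, e] <- stats::rbinom(n, 1L, pmin(prob, 1))
  }

  roles <- names(config$suspect_role_distribution)
  role_mat <- matrix(
    sample(roles, n * length(dv), replace = TRUE,
           prob = config$suspect_role_distribution),
    nrow = n
  )

  n_dup <- floor(config$duplicate_fraction * n)
  dup <- rep(FALSE, n)
  if (n_dup > 0) dup[sample.int(n, n_dup)] <- TRUE

  age <- pmax(15L, pmin(60L, as.integer(round(stats::rnorm(n, 28, 8)))))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.85, 0.15))
  event_dt <- sprintf(
    "%04d%02d%02d", quarter_year(quarter), (quarter_num(quarter) - 1L) * 3L +
      sample(1:3, n, replace = TRUE), sample(1:28, n, replace = TRUE)
  )

  list(
    n = n, idx = idx, drug_mat = drug_mat, event_mat = event_mat,
    role_mat = role_mat, dup = dup, age = age, sex = sex, event_dt = event_dt
  )
}

# filler names used when a case draws no vocabulary drug/event; deliberately
# outside the vocabularies so configured marginals stay exact
FILLER_DRUG <- "UNSPECIFIED MEDICATION"
FILLER_PT <- "Drug ineffective"

#' Generate one synthetic quarter as DEMO/DRUG/REAC files
#'
#' Writes the three "$"-delimited quarterly files for `quarter` into `dir`,
#' in the dialect matching the quarter's era (legacy ISR-keyed before 2012Q4,
#' modern primaryid/caseid-keyed from 2012Q4 on) unless overridden. Every
#' case id appears in all three files with at least one drug and one reaction
#' row; duplicated cases appear as two versions of one case id, identical
#' except for an incremented age and a follow-up flag.
#'
#' @param config a [synth_config()].
#' @param quarter one of `config$quarters`.
#' @param dir output directory (created if needed).
#' @param dialect `NULL` for era-based choice, or `"legacy"`/`"modern"`.
#' @return invisibly, a named character vector of the three file paths
#'   (`demo`, `drug`, `reac`).
#' @export
generate_quarter <- function(config, quarter, dir, dialect = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (length(quarter) != 1L || !is_quarter_label(quarter)) {
    stop("quarter must be a single label matching \"YYYYQn\"; got ",
         deparse(quarter))
  }
  if (!quarter %in% config$quarters) {
    stop("quarter ", quarter, " is not in config$quarters")
  }
  dialect <- dialect %||% quarter_era(quarter)
  dialect <- match.arg(dialect, c("legacy", "modern"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_cases(config, quarter)
  n <- sim$n
  # doubles: composite keys (case * 100 + version) can exceed 32-bit range
  case_num <- sim$idx * 1e7 + as.double(seq_len(n))

  # one block of demo/drug/reac rows per emitted version
  emit_version <- function(keep, ver) {
    ids <- which(keep)
    dm <- sim$drug_mat[ids, , drop = FALSE]
    em <- sim$event_mat[ids, , drop = FALSE]
    dlist <- lapply(seq_along(ids), function(r) {
      drugs <- colnames(dm)[dm[r, ] == 1L]
      roles <- sim$role_mat[ids[r], dm[r, ] == 1L]
      if (!length(drugs)) {
        drugs <- FILLER_DRUG
        roles <- "C"
      }
      list(drugs = drugs, roles = roles)
    })
    elist <- lapply(seq_along(ids), function(r) {
      evs <- colnames(em)[em[r, ] == 1L]
      if (!length(evs)) evs <- FILLER_PT
      evs
    })
    ndrug <- vapply(dlist, function(x) length(x$drugs), integer(1))
    nreac <- lengths(elist)
    list(
      case = case_num[ids], ver = ver,
      age = sim$age[ids] + (ver - 1L), sex = sim$sex[ids],
      event_dt = sim$event_dt[ids], i_f = if (ver == 1L) "I" else "F",
      drug_case = rep(case_num[ids], ndrug),
      drug_seq = unlist(lapply(ndrug, seq_len)),
      drug_name = unlist(lapply(dlist, `[[`, "drugs")),
      drug_role = unlist(lapply(dlist, `[[`, "roles")),
      reac_case = rep(case_num[ids], nreac),
      reac_pt = unlist(elist)
    )
  }

  v1 <- emit_version(rep(TRUE, n), 1L)
  blocks <- list(v1)
  if (any(sim$dup)) blocks <- c(blocks, list(emit_version(sim$dup, 2L)))

  stem <- quarter_stem(quarter)
  paths <- c(
    demo = file.path(dir, paste0("DEMO", stem, ".txt")),
    drug = file.path(dir, paste0("DRUG", stem, ".txt")),
    reac = file.path(dir, paste0("REAC", stem, ".txt"))
  )

  fmt <- function(...) paste(..., sep = "$")
  id <- function(x) sprintf("%.0f", x)  # avoid scientific notation
  demo_lines <- character(0)
  drug_lines <- character(0)
  reac_lines <- character(0)
  for (b in blocks) {
    if (dialect == "legacy") {
      demo_lines <- c(demo_lines, fmt(
        id(b$case * 100 + b$ver), id(b$case), b$i_f, b$ver, b$age, "YR",
        b$sex, b$event_dt
      ))
      drug_lines <- c(drug_lines, fmt(
        id(b$drug_case * 100 + b$ver), b$drug_seq, b$drug_role,
        b$drug_name, "ORAL"
      ))
      reac_lines <- c(reac_lines, fmt(id(b$reac_case * 100 + b$ver), b$reac_pt))
    } else {
      demo_lines <- c(demo_lines, fmt(
        id(b$case * 10 + b$ver), id(b$case), b$ver, b$i_f, b$age, "YR",
        b$sex, b$event_dt
      ))
      drug_lines <- c(drug_lines, fmt(
        id(b$drug_case * 10 + b$ver), id(b$drug_case), b$drug_seq,
        b$drug_role, b$drug_name, "ORAL"
      ))
      reac_lines <- c(reac_lines, fmt(
        id(b$reac_case * 10 + b$ver), id(b$reac_case), b$reac_pt
      ))
    }
  }

  headers <- if (dialect == "legacy") {
    list(
      demo = "ISR$CASE$I_F_COD$FOLL_SEQ$AGE$AGE_COD$GNDR_COD$EVENT_DT",
      drug = "ISR$DRUG_SEQ$ROLE_COD$DRUGNAME$ROUTE",
      reac = "ISR$PT"
    )
  } else {
    list(
      demo = "primaryid$caseid$caseversion$i_f_code$age$age_cod$sex$event_dt",
      drug = "primaryid$caseid$drug_seq$role_cod$drugname$route",
      reac = "primaryid$caseid$pt"
    )
  }
  writeLines(c(headers$demo, demo_lines), paths[["demo"]])
  writeLines(c(headers$drug, drug_lines), paths[["drug"]])
  writeLines(c(headers$reac, reac_lines), paths[["reac"]])
  invisible(paths)
}

#' Generate a full synthetic dataset (all quarters plus ground truth)
#'
#' Calls [generate_quarter()] for every quarter in the configuration and
#' writes a `ground_truth.csv` sidecar holding [expected_counts()] so that
#' downstream estimates can be compared with the generative truth.
#'
#' @inheritParams generate_quarter
#' @param dir output directory.
#' @return invisibly, a list with `files` (matrix of per-quarter paths) and
#'   `ground_truth` (path of the sidecar).
#' @export
generate_dataset <- function(config, dir, dialect = NULL) {
  stopifnot(inherits(config, "synth_config"))
  files <- vapply(
    config$quarters,
    function(q) generate_quarter(config, q, dir, dialect = dialect),
    character(3)
  )
  gt <- expected_counts(config)
  gt_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(gt, gt_path, row.names = FALSE, quote = FALSE)
  invisible(list(files = files, ground_truth = gt_path))
}

#' Closed-form expected counts and true association strengths
#'
#' For every (drug, event) pair of the vocabularies, returns the expected
#' contingency counts over the full configured dataset under the generative
#' model: `e_nj = N p_d` (drug margin), `e_nij = N p_d q1` and
#' `e_ni = N (p_d q1 + (1 - p_d) q0)` where `q1`/`q0` are the event
#' probabilities given drug presence/absence (the planted `rate_ratio`
#' multiplies the event probability when its drug is present; independent
#' planted drugs on the same event enter multiplicatively). `true_ror` is
#' the model's exact odds ratio `[q1/(1-q1)] / [q0/(1-q0)]` — the estimand
#' of the reporting odds ratio — while `rate_ratio` is the planted risk
#' ratio `q1/q0`; the two coincide as the event probability tends to 0.
#'
#' @param config a [synth_config()].
#' @return a data.frame with one row per (drug, event) pair: `drug`, `event`,
#'   `rate_ratio`, `e_nij`, `e_ni`, `e_nj`, `n_total`, `true_ror`.
#' @export
expected_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dv <- config$drug_vocabulary
  ev <- config$event_vocabulary
  pa <- config$planted_associations
  n_total <- config$n_cases_per_quarter * length(config$quarters)

  grid <- expand.grid(
    drug = names(dv), event = names(ev),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$drug[i]; e <- grid$event[i]
    p_d <- dv[[d]]; p_e <- ev[[e]]
    planted <- pa[pa$event == e, , drop = FALSE]
    rr <- if (d %in% planted$drug) planted$rate_ratio[planted$drug == d] else 1
    # expectation over presence of the *other* planted drugs for this event
    others <- planted[planted$drug != d, , drop = FALSE]
    f_other <- if (nrow(others)) {
      prod(1 - dv[others$drug] + dv[others$drug] * others$rate_ratio)
    } else 1
    q1 <- min(1, p_e * rr * f_other)
    q0 <- min(1, p_e * f_other)
    true_ror <- if (q0 > 0 && q1 < 1) (q1 / (1 - q1)) / (q0 / (1 - q0)) else NA_real_
    data.frame(
      drug = d, event = e, rate_ratio = rr,
      e_nij = n_total * p_d * q1,
      e_ni = n_total * (p_d * q1 + (1 - p_d) * q0),
      e_nj = n_total * p_d,
      n_total = n_total,
      true_ror = true_ror
    )
  })
  out <- do.call(rbind, res)
  stopifnot(all(out$e_nij <= pmin(out$e_ni, out$e_nj) + 1e-9))
  out
}

#' Simulate contingency counts for one drug--event pair
#'
#' A count-level shortcut through the same generative model as
#' [generate_quarter()] for replicate studies (confidence-interval coverage,
#' null calibration) where writing and re-parsing files would add nothing:
#' the number of drug cases is Binomial(n, p_drug), events among them
#' Binomial(n_j, q1) with `q1 = min(1, rate_ratio * p_event)`, and events
#' among the remaining cases Binomial(n - n_j, p_event).
#'
#' @param n_cases total cases per replicate.
#' @param p_drug,p_event marginal probabilities.
#' @param rate_ratio planted reporting-rate ratio (1 = independence).
#' @param n_rep number of replicates.
#' @param seed optional integer seed.
#' @return data.frame with columns `n_ij`, `n_i`, `n_j`, `n`, one row per
#'   replicate.
#' @export
simulate_pair_counts <- function(n_cases, p_drug, p_event, rate_ratio = 1,
                                 n_rep = 1, seed = NULL) {
  stopifnot(
    n_cases >= 1, p_drug >= 0, p_drug <= 1, p_event >= 0, p_event <= 1,
    rate_ratio >= 0, n_rep >= 1
  )
  q1 <- rate_ratio * p_event
  if (q1 > 1 + 1e-12) {
    stop("rate_ratio * p_event = ", signif(q1, 4), " exceeds 1")
  }
  q1 <- min(1, q1)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  n_j <- stats::rbinom(n_rep, n_cases, p_drug)
  n_ij <- stats::rbinom(n_rep, n_j, q1)
  n_i_rest <- stats::rbinom(n_rep, n_cases - n_j, p_event)
  data.frame(n_ij = n_ij, n_i = n_ij + n_i_rest, n_j = n_j, n = n_cases)
}

#' True odds ratio implied by a planted rate ratio
#'
#' @param p_event marginal event probability.
#' @param rate_ratio planted risk ratio.
#' @return the exact odds ratio the ROR estimates under the generative model.
#' @export
true_odds_ratio <- function(p_event, rate_ratio) {
  q1 <- min(1, rate_ratio * p_event)
  q0 <- p_event
  (q1 / (1 - q1)) / (q0 / (1 - q0))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  cases/quarter:", x$n_cases_per_quarter,
      " quarters:", length(x$quarters),
      paste0("(", x$quarters[1], "..", x$quarters[length(x$quarters)], ")\n"))
  cat("  drugs:", length(x$drug_vocabulary),
      " events:", length(x$event_vocabulary),
      " planted pairs:", nrow(x$planted_associations), "\n")
  cat("  duplicate_fraction:", x$duplicate_fraction, " seed:", x$seed, "\n")
  invisible(x)
}
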