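#' Published reference signal values for levonorgestrel
#'
#' Point estimates (IC, ROR, PRR) and, where published, 95% interval bounds
#' for the 15 clinically reviewed preferred terms of a published
#' levonorgestrel screen of the FDA spontaneous-report database (reports
#' 2006Q1--2015Q2), shipped as a plain-text fixture. `n_reports` is the
#' published case count per PT for the ten reproductive-system terms.
#' Values are stored exactly as printed; note that the source prints some
#' ROR/PRR point values at or below zero for the non-signal terms, so these
#' columns are screening scores to be compared against their null values
#' (0 for IC, 1 for ROR/PRR), not recomputable ratio estimates.
#'
#' @return data.frame with columns `pt`, `group`, `n_reports`, `ic`, `ror`,
#'   `prr`, `ror_low`, `ror_high`, `prr_low`, `prr_high`, `ic_low`,
#'   `ic_high`.
#' @seealso [classify_point_fixtures()]
#' @export
reference_signal_values <- function() {
  path <- system.file("extdata", "levonorgestrel_reference_signals.csv",
                      package = "faersignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify published point values against null-value rules
#'
#' Applies the point-value screening rules to a table of published (IC,
#' ROR, PRR) triples: a term is point-positive when `IC > 0`, `ROR > 1`
#' and `PRR > 1` all hold. Where interval lower bounds are available the
#' interval rules (`ror_low > 1`, `prr_low > 1`, `ic_low > 0`) are
#' evaluated too, as `NA` otherwise.
#'
#' @param values a data.frame shaped like [reference_signal_values()]
#'   (the default).
#' @return data.frame with one row per PT: the inputs plus `point_ic`,
#'   `point_ror`, `point_prr`, `point_positive`, and `lb_ror`, `lb_prr`,
#'   `lb_ic` interval flags.
#' @export
#' @examples
#' dec <- classify_point_fixtures()
#' sum(dec$point_positive)
classify_point_fixtures <- function(values = reference_signal_values()) {
  need <- c("pt", "ic", "ror", "prr")
  if (!all(need %in% names(values))) {
    stop("values needs columns ", paste(need, collapse = ", "))
  }
  out <- values
  out$point_ic <- out$ic > 0
  out$point_ror <- out$ror > 1
  out$point_prr <- out$prr > 1
  out$point_positive <- out$point_ic & out$point_ror & out$point_prr
  lb <- function(x, null) if (is.null(x)) NA else ifelse(is.na(x), NA, x > null)
  out$lb_ror <- lb(out$ror_low, 1)
  out$lb_prr <- lb(out$prr_low, 1)
  out$lb_ic <- lb(out$ic_low, 0)
  out
}
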