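# writes a small modern-dialect quarter from row vectors
write_modern_quarter <- function(dir, demo, drug, reac, stem = "13Q1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("primaryid$caseid$caseversion$i_f_code$age$age_cod$sex$event_dt",
               demo), file.path(dir, paste0("DEMO", stem, ".txt")))
  writeLines(c("primaryid$caseid$drug_seq$role_cod$drugname$route",
               drug), file.path(dir, paste0("DRUG", stem, ".txt")))
  writeLines(c("primaryid$caseid$pt",
               reac), file.path(dir, paste0("REAC", stem, ".txt")))
  dir
}

test_that("suspect-role filtering excludes concomitant-only cases", {
  d <- write_modern_quarter(
    tempfile(),
    demo = c("101$10$1$I$30$YR$F$20130105",
             "201$20$1$I$28$YR$F$20130110",
             "301$30$1$I$31$YR$F$20130111"),
    drug = c("101$10$1$C$LEVONORGESTREL$ORAL",        # concomitant only
             "201$20$1$PS$LEVONORGESTREL$ORAL",       # PS and C rows
             "201$20$2$C$LEVONORGESTREL$ORAL",
             "301$30$1$SS$IBUPROFEN$ORAL"),
    reac = c("101$10$Headache", "201$20$Nausea", "301$30$Headache")
  )
  cs <- deduplicate_cases(read_quarter_dir(d))
  ids <- select_drug_cases(cs, drug_query("levonorgestrel"))
  expect_identical(ids, "20")  # case 10 excluded, case 20 counted once
  # widening the role set can only enlarge the selection
  ids_all <- select_drug_cases(cs, drug_query(
    "levonorgestrel", roles = c("PS", "SS", "C", "I")))
  expect_true(all(ids %in% ids_all))
  expect_setequal(ids_all, c("10", "20"))
})

test_that("substring and exact matching behave as documented", {
  d <- write_modern_quarter(
    tempfile(),
    demo = c("101$10$1$I$30$YR$F$20130105", "201$20$1$I$28$YR$F$20130110"),
    drug = c("101$10$1$PS$LEVONORGESTREL TABLETS 1.5MG$ORAL",
             "201$20$1$PS$Levonorgestrel$ORAL"),
    reac = c("101$10$Headache", "201$20$Nausea")
  )
  cs <- deduplicate_cases(read_quarter_dir(d))
  expect_setequal(
    select_drug_cases(cs, drug_query("levonorgestrel")), c("10", "20")
  )
  expect_identical(
    select_drug_cases(cs, drug_query("levonorgestrel",
                                     match_mode = "exact")), "20"
  )
  # synonyms extend the name set
  expect_setequal(
    select_drug_cases(cs, drug_query("plan b",
                                     synonyms = "levonorgestrel")),
    c("10", "20")
  )
  expect_error(drug_query("", synonyms = character()), "non-empty")
})

test_that("deduplication keeps only the latest version of a case", {
  # v1 reports event A with drug X; v2 revises to event B with drug Y
  d <- write_modern_quarter(
    tempfile(),
    demo = c("101$10$1$I$30$YR$F$20130105",
             "102$10$2$F$31$YR$F$20130105",
             "201$20$1$I$28$YR$F$20130110"),
    drug = c("101$10$1$PS$DRUGX$ORAL",
             "102$10$1$PS$DRUGY$ORAL",
             "201$20$1$PS$DRUGX$ORAL"),
    reac = c("101$10$Event A", "102$10$Event B", "201$20$Event A")
  )
  cs <- deduplicate_cases(read_quarter_dir(d))
  expect_equal(nrow(cs$cases), 2)
  expect_equal(cs$n_reports, 3)
  expect_equal(cs$n_collapsed, 1)
  ev10 <- cs$case_events[case_id == "10"]
  expect_identical(ev10$pt, "Event B")
  expect_identical(cs$case_drugs[case_id == "10", drug_name], "DRUGY")
  # dedup off: each version is its own case
  cs_off <- deduplicate_cases(read_quarter_dir(d), mode = "off")
  expect_equal(nrow(cs_off$cases), 3)
  expect_equal(cs_off$n_collapsed, 0)
})

test_that("dedup restores the configured number of unique cases", {
  cfg <- synth_config(
    1000, "2013Q1", c(drugx = 0.2), c("Event A" = 0.1),
    duplicate_fraction = 0.2, seed = 4
  )
  d <- tempfile()
  generate_quarter(cfg, "2013Q1", d)
  b <- read_quarter_dir(d)
  expect_equal(nrow(b[[1]]$demo_rows), 1200)
  cs <- deduplicate_cases(b)
  expect_equal(nrow(cs$cases), 1000)
  expect_equal(cs$n_collapsed, 200)
  # zero-duplicate input: dedup is the identity
  cfg0 <- synth_config(300, "2013Q1", c(drugx = 0.2), c("Event A" = 0.1),
                       duplicate_fraction = 0, seed = 4)
  d0 <- tempfile()
  generate_quarter(cfg0, "2013Q1", d0)
  cs0 <- deduplicate_cases(read_quarter_dir(d0))
  expect_equal(nrow(cs0$cases), 300)
  expect_equal(cs0$n_collapsed, 0)
})

test_that("a PT repeated within one case contributes a single count", {
  d <- write_modern_quarter(
    tempfile(),
    demo = c("101$10$1$I$30$YR$F$20130105"),
    drug = c("101$10$1$PS$DRUGX$ORAL"),
    reac = c("101$10$Headache", "101$10$HEADACHE", "101$10$ headache ")
  )
  cs <- deduplicate_cases(read_quarter_dir(d))
  ft <- tally_events(cs, "10")
  expect_equal(nrow(ft), 1)
  expect_equal(ft$count, 1)
  expect_equal(ft$total, 1)
})

test_that("tallies carry explicit zeros and empty selections give empty tables", {
  cfg <- small_config(n = 200)
  d <- tempfile()
  generate_dataset(cfg, d)
  cs <- deduplicate_cases(read_quarter_dir(d))
  ids <- select_drug_cases(cs, drug_query("levonorgestrel"))
  ft <- tally_events(cs, ids)
  # every (pt, quarter) combination present, zero or not
  combos <- table(ft$pt)
  expect_true(all(combos == length(unique(ft$quarter))))
  expect_true(all(ft$count >= 0))
  # total is the sum over quarters
  agg <- tapply(ft$count, ft$pt_key, sum)
  expect_equal(as.vector(agg[ft$pt_key]), as.vector(ft$total))
  ft0 <- tally_events(cs, character(0))
  expect_equal(nrow(ft0), 0)
})

test_that("selection and tallies agree exactly with a brute-force recount", {
  cfg <- small_config(n = 400, rate_ratio = 6, duplicate_fraction = 0.15)
  d <- tempfile()
  generate_dataset(cfg, d)
  cs <- deduplicate_cases(read_quarter_dir(d))
  ids <- select_drug_cases(cs, drug_query("levonorgestrel"))
  bf <- brute_force_counts(d, "levonorgestrel", c("PS", "SS"),
                           "Menstruation delayed")
  expect_identical(sort(ids), bf$drug_cases)
  t <- build_table("Menstruation delayed", ids, cs)
  expect_equal(t$n, bf$n)
  expect_equal(t$n_j, bf$n_j)
  expect_equal(t$n_i, bf$n_i)
  expect_equal(t$n_ij, bf$n_ij)
})

test_that("frequency table CSV writer orders PTs alphabetically", {
  cfg <- small_config(n = 150)
  d <- tempfile()
  generate_dataset(cfg, d)
  cs <- deduplicate_cases(read_quarter_dir(d))
  ids <- select_drug_cases(cs, drug_query("levonorgestrel"))
  out <- tempfile(fileext = ".csv")
  write_frequency_table(tally_events(cs, ids), out)
  x <- read.csv(out)
  expect_named(x, c("pt", "quarter", "count", "total"))
  expect_false(is.unsorted(x$pt))
})
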