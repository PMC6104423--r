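tab <- function(a, b, c, d) {
  contingency_table(n_ij = a, n_i = a + c, n_j = a + b, n = a + b + c + d)
}

test_that("contingency tables enforce their cell invariants", {
  t <- contingency_table(n_ij = 20, n_i = 120, n_j = 100, n = 10000)
  expect_equal(c(t$a, t$b, t$c, t$d), c(20, 80, 100, 9800))
  expect_equal(t$a + t$b + t$c + t$d, t$n)
  expect_error(contingency_table(50, 40, 100, 10000), "negative")
  expect_error(contingency_table(0, 0, 0, 0), "n must be >= 1")
})

test_that("ROR matches hand evaluation of the cross-product and SE formulas", {
  t <- tab(20, 80, 100, 9800)
  r <- compute_ror(t)
  expect_equal(r$estimate, 24.5)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 9800)
  expect_equal(r$se_log, se)
  expect_equal(r$low, exp(log(24.5) - 1.96 * se))
  expect_equal(r$high, exp(log(24.5) + 1.96 * se))
  expect_false(r$correction_applied)
  # symmetric table: ROR 1, CI symmetric about 1 on the log scale
  s <- compute_ror(tab(10, 10, 10, 10))
  expect_equal(s$estimate, 1)
  expect_equal(log(s$high), -log(s$low))
})

test_that("PRR matches hand evaluation and equals 1 for equal proportions", {
  p <- compute_prr(tab(20, 80, 100, 9800))
  expect_equal(p$estimate, (20 / 100) / (100 / 9900))  # 19.8
  expect_equal(p$se_log, sqrt(1 / 20 - 1 / 100 + 1 / 100 - 1 / 9900))
  eq <- compute_prr(tab(5, 45, 20, 180))  # both proportions 0.1
  expect_equal(eq$estimate, 1)
})

test_that("zero cells trigger the continuity correction or explicit undefined", {
  t0 <- tab(0, 10, 10, 100)
  r <- compute_ror(t0)
  expect_true(r$correction_applied)
  expect_equal(r$estimate, (0.5 * 100.5) / (10.5 * 10.5))
  r_off <- compute_ror(t0, continuity = FALSE)
  expect_false(r_off$defined)
  expect_true(is.na(r_off$estimate))
  expect_match(r_off$reason, "zero cell")
  p_off <- compute_prr(t0, continuity = FALSE)
  expect_false(p_off$defined)
  # nonzero tables are never perturbed
  expect_false(compute_ror(tab(1, 1, 1, 1))$correction_applied)
})

test_that("chi-squared equals the classic Yates formula and chisq.test", {
  # exact independence: uncorrected statistic is 0
  expect_equal(compute_chi2(tab(10, 90, 100, 900), correct = FALSE)$statistic, 0)
  # invariance under simultaneous row and column swap
  t1 <- compute_chi2(tab(20, 80, 100, 9800))$statistic
  t2 <- compute_chi2(tab(9800, 100, 80, 20))$statistic
  expect_equal(t1, t2)
  # grid cross-check against stats::chisq.test as an independent oracle
  cells <- expand.grid(a = c(1, 3, 17), b = c(2, 40), c = c(5, 33),
                       d = c(11, 950))
  for (i in seq_len(nrow(cells))) {
    w <- cells[i, ]
    m <- matrix(c(w$a, w$c, w$b, w$d), 2, 2)
    expect_equal(
      compute_chi2(tab(w$a, w$b, w$c, w$d))$statistic,
      unname(suppressWarnings(stats::chisq.test(m, correct = TRUE)$statistic)),
      tolerance = 1e-12
    )
    expect_equal(
      compute_chi2(tab(w$a, w$b, w$c, w$d), correct = FALSE)$statistic,
      unname(suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)),
      tolerance = 1e-12
    )
  }
  z <- compute_chi2(tab(0, 0, 5, 5))
  expect_false(z$defined)
})

test_that("information component follows the shrinkage observed/expected form", {
  # unshrunk form at hand-computed value
  t <- contingency_table(n_ij = 20, n_i = 120, n_j = 100, n = 10000)
  ic <- compute_ic(t, shrink = FALSE)
  expect_equal(ic$ic, log2(20 * 10000 / (120 * 100)))
  expect_equal(ic$sd, 1 / (log(2) * sqrt(20)))
  # exact independence, unshrunk: IC = 0
  t0 <- contingency_table(n_ij = 10, n_i = 100, n_j = 1000, n = 10000)
  expect_equal(compute_ic(t0, shrink = FALSE)$ic, 0)
  # zero joint count: shrinkage keeps IC finite and negative
  tz <- contingency_table(n_ij = 0, n_i = 50, n_j = 100, n = 10000)
  icz <- compute_ic(tz)
  expect_true(icz$defined)
  expect_equal(icz$ic, log2(0.5 / (50 * 100 / 10000 + 0.5)))
  expect_lt(icz$ic, 0)
  # zero margins are undefined, signalled
  expect_false(compute_ic(contingency_table(0, 0, 10, 100))$defined)
})

test_that("transposition identity: ror(a,b,c,d) = 1/ror(b,a,d,c)", {
  grid <- expand.grid(a = c(1, 5, 20), b = c(2, 50), c = c(3, 70),
                      d = c(10, 400))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r1 <- compute_ror(tab(g$a, g$b, g$c, g$d))$estimate
    r2 <- compute_ror(tab(g$b, g$a, g$d, g$c))$estimate
    expect_equal(r1, 1 / r2)
  }
})

test_that("ROR and PRR are strictly increasing in the joint count", {
  rors <- prrs <- numeric(0)
  for (a in 1:15) {
    t <- tab(a, 50, 30, 900)
    rors <- c(rors, compute_ror(t)$estimate)
    prrs <- c(prrs, compute_prr(t)$estimate)
  }
  expect_true(all(diff(rors) > 0))
  expect_true(all(diff(prrs) > 0))
})

test_that("PRR approaches ROR in the rare-event regime", {
  # sweep of tables with event proportion < 1%: relative gap below 5%
  for (n_j in c(200, 1000)) {
    for (frac in c(0.001, 0.005, 0.009)) {
      n <- 2e5
      n_i <- round(frac * n)
      a <- round(frac * n_j * 3)  # threefold disproportion
      t <- contingency_table(n_ij = a, n_i = n_i, n_j = n_j, n = n)
      ror <- compute_ror(t)$estimate
      prr <- compute_prr(t)$estimate
      expect_lt(abs(ror - prr) / prr, 0.05)
    }
  }
})

test_that("classification applies the three criteria with strict bounds", {
  crit <- signal_criteria()
  m <- signal_metrics(tab(20, 80, 100, 9800))
  d <- classify_signal(m, crit)
  expect_true(d$prr_chi2_n && d$ic_positive && d$ror_positive && d$overall)

  # n below the minimum-report threshold fails the count criterion only
  m2 <- signal_metrics(tab(2, 8, 100, 9800))
  d2 <- classify_signal(m2, crit)
  expect_false(d2$prr_chi2_n)
  expect_false(d2$overall)

  # a boundary ROR lower bound of exactly 1 is not a signal
  m3 <- m
  m3$ror_low <- 1
  d3 <- classify_signal(m3, crit)
  expect_false(d3$ror_positive)

  # undefined metrics fail their criterion with a recorded reason
  m4 <- signal_metrics(tab(0, 10, 10, 100), continuity = FALSE)
  d4 <- classify_signal(m4, crit)
  expect_false(d4$overall)
  expect_true(length(d4$reasons) > 0)

  expect_error(signal_criteria(prr_threshold = 0), "positive|not TRUE")
})

test_that("signal tables rank by joint count with alphabetical tie-break", {
  cfg <- small_config(n = 600)
  d <- tempfile()
  generate_dataset(cfg, d)
  cs <- deduplicate_cases(read_quarter_dir(d))
  ids <- select_drug_cases(cs, drug_query("levonorgestrel"))
  st <- signal_table(cs, ids)
  expect_true(all(diff(st$n_ij) <= 0))
  ties <- split(st$pt, st$n_ij)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
  out <- tempfile(fileext = ".csv")
  write_signal_table(st, out)
  x <- read.csv(out)
  expect_equal(names(x)[1:5], c("pt", "n_ij", "n_i", "n_j", "n"))
})
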