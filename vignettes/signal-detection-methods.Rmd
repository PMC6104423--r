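---
title: "Disproportionality signal detection on spontaneous-report streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous-report streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA's FAERS collect
case reports in which health professionals or consumers name one or more
*suspect drugs* and one or more adverse events coded as MedDRA preferred
terms (PTs). Because there is no denominator of exposed patients,
post-marketing safety screening works by *disproportionality*: a drug–event
pair is interesting when it is reported more often than the pair's margins
would predict under independence within the database itself.

For a drug $j$ and event $i$, counting **distinct deduplicated cases**, the
2×2 table is

|              | event $i$        | not event $i$      |
|--------------|------------------|--------------------|
| drug $j$     | $a = N_{ij}$     | $b = N_j - N_{ij}$ |
| other drugs  | $c = N_i-N_{ij}$ | $d = N-N_i-N_j+N_{ij}$ |

and the package computes four screening statistics:

* **ROR** (reporting odds ratio): $\mathrm{ROR} = ad/bc$, with
  $\mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{1/a + 1/b + 1/c + 1/d}$ and 95%
  bounds $\exp(\ln \mathrm{ROR} \pm 1.96\,\mathrm{SE})$.
* **PRR** (proportional reporting ratio):
  $\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$, with
  $\mathrm{SE}(\ln \mathrm{PRR}) = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$.
* **χ²**: the Yates-corrected statistic
  $n(|ad-bc| - n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]$, floored at zero. The Yates
  form is the default because the classic PRR screening criterion was
  defined with it; the uncorrected Pearson statistic is available by flag.
* **IC** (information component): the shrinkage form
  $\mathrm{IC} = \log_2 \frac{N_{ij} + 1/2}{E + 1/2}$ with
  $E = N_i N_j / N$, and delta-method spread
  $\mathrm{SD} = 1/(\ln 2\sqrt{N_{ij} + 1/2})$. The +1/2 shrinkage keeps the
  measure finite at $N_{ij}=0$ and pulls small counts toward zero
  association, which is what makes the IC usable as a routine screen; the
  plain $\log_2$ observed/expected form is available by flag for tables
  with $N_{ij} > 0$.

A pair is **flagged overall** when all three criteria hold:

1. $\mathrm{PRR} \ge 2$ and $\chi^2 \ge 4$ and $N_{ij} \ge 3$;
2. $\mathrm{IC} - 2\,\mathrm{SD} > 0$;
3. $\mathrm{ROR} - 1.96\,\mathrm{SE} > 1$, i.e. the ROR 95% lower bound
   exceeds 1 (strict inequalities in both interval rules).

A flag is a screening signal, not evidence of causation: reporting is
subject to the Weber effect (a surge after launch) and notoriety bias
(surges after publicity), neither of which the statistics correct for.

## Numerical choices

* **Continuity correction.** When any cell of the table is zero, 0.5 is
  added to all four cells before computing ROR/PRR, and the fact is flagged
  in the output. Nonzero tables are never perturbed, so estimates on
  well-populated tables are exactly the textbook values. With the
  correction disabled, a zero cell yields an explicitly *undefined* result
  (`NA` plus a reason), never a silent zero — an undefined statistic fails
  its criterion during classification.
* **CI form.** Interval bounds are always
  $\exp(\ln\widehat\theta \pm 1.96\,\mathrm{SE})$; some secondary sources
  typeset this formula with the SE factor dropped, but the
  $\mathrm{ROR} - 1.96\,\mathrm{SE} > 1$ decision rule fixes the intended
  reading.
* **Denominator semantics.** $N$ is the number of distinct deduplicated
  cases across the analysed quarters. Counting drug–event *pair mentions*
  instead would inflate $N$ and is deliberately not offered.
* **Ranking.** Signal tables are sorted by $N_{ij}$ descending with
  alphabetical PT tie-break, so the most-reported pairs surface first and
  output order is deterministic.

## From quarterly files to cases

FAERS quarterly extracts are "$"-delimited DEMO/DRUG/REAC text files whose
layout changed at 2012Q4: before, all files are keyed by `ISR` (one id per
report version; the stable case id is DEMO's `CASE` column), after, files
carry `primaryid` (version key) and `caseid`, with `caseversion` in DEMO.
`read_quarter()` supports both dialects through a column-mapping table and
auto-detects them from the header. Within-study choices:

* **Malformed rows** (wrong field count, e.g. an embedded delimiter in a
  drug name) are counted and sampled into a rejects report, never silently
  dropped; files are read as UTF-8 with a counted latin-1 fallback.
* **Deduplication** keeps, per case id, the report with the highest version
  (ties broken by the larger key — in the legacy dialect the version is the
  rank of the ISR within its case, since a follow-up is a new ISR). The
  alternative `off` mode treats every version as a case, because public
  analyses differ on whether they deduplicate at all.
* **Role filtering.** A case is attributed to the query drug only if a
  matching drug row carries an included role code; the default
  `{PS, SS}` keeps primary and secondary suspects and drops concomitant or
  interacting mentions. Drug matching is case-insensitive substring by
  default (catching salt and brand decorations), with an exact mode.
* **Events are sets.** A PT repeated within one case counts once; event
  frequencies are distinct-case counts per quarter with explicit zeros.
* The human step of choosing which PTs are clinically relevant enters only
  as an optional whitelist in `run_config()`; it is never computed.

## The synthetic report stream

Real quarterly extracts are large and external, so the package ships a
generator whose ground truth is known in closed form, making every
downstream stage testable. Per case, each vocabulary drug is an independent
Bernoulli draw with its marginal probability; each event is Bernoulli with
its marginal probability multiplied by `rate_ratio` for every planted
association whose drug the case contains. Thus `rate_ratio` is the true
reporting-rate (risk) ratio of the pair, `rate_ratio = 1` is exact
independence, and `expected_counts()` returns the implied
$E[N_{ij}], E[N_i], E[N_j]$ and the exact odds ratio
$\frac{q_1/(1-q_1)}{q_0/(1-q_0)}$ that the ROR estimates (slightly above
the risk ratio for non-rare events). Configurations whose conditional event
probability would exceed 1 are rejected at construction rather than
silently clamped, so the closed form always describes what the generator
does.

Other emulated features: a configurable fraction of cases is emitted twice
under one case id with consecutive versions and a perturbed age (so
deduplication is observable); drug mentions get role codes from a
configurable PS/SS/C/I distribution; cases that draw no vocabulary drug or
event receive filler rows (a concomitant "unspecified medication", a
"drug ineffective" PT) so every case appears in all three files without
touching the vocabulary marginals; age and sex are generated but play no
statistical role. Identical seed and configuration give byte-identical
files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: drug co-prescription structure, reporter and
demographic biases, secular reporting trends (Weber effect, notoriety
bias), verbatim drug-name noise needing ingredient mapping, and MedDRA
hierarchy effects. Results on synthetic streams validate the *machinery*,
not the epidemiology.

`simulate_pair_counts()` is a count-level shortcut through the same model
(binomial draws of $N_j$, $N_{ij}$, $N_i - N_{ij}$) used for replicate
studies such as CI-coverage checks, where writing and re-parsing thousands
of file sets would add nothing.

## Published reference fixture

`reference_signal_values()` ships the point estimates (IC, ROR, PRR), the
published 95% bounds, and the report counts for the 15 clinically reviewed
PTs of a published levonorgestrel screen of FAERS (2006Q1–2015Q2), and
`classify_point_fixtures()` applies point-value null rules (IC > 0,
ROR > 1, PRR > 1), under which exactly the ten reproductive-system terms
are positive. Two caveats are preserved deliberately: the source prints
ROR/PRR point values at or below zero for some non-signal terms
(impossible for a ratio) and IC values far above any $\log_2$
observed/expected scale, so the fixture columns are treated as screening
scores to compare against their null values, exactly as printed, and no
attempt is made to reverse-engineer the underlying tables. Where the table
and the accompanying prose disagree in the last digit (three terms), the
table's point values are used; the classification outcome is unaffected.

## Verification strategy and problem sizes

The test suite validates each stage against an independent oracle:
statistics on a grid of >100 small tables against hand-written textbook
formulas and `stats::chisq.test`; parser and case assembly against a
base-R brute-force recount of the raw files; generator calibration against
binomial 99% bands over 20 seeds and 3-Poisson-SD bands on a 50,000-case
quarter; ROR CI coverage against the generative odds ratio on 500
replicates of 50,000 cases per rate ratio in {1, 2, 4} (accepting 95% ± 3%
coverage, and an overall-flag rate below 5% at independence); and the full
pipeline against brute force on a 10,000-case four-quarter dataset spanning
both file dialects, with byte-identical rerun outputs. These sizes keep the
whole suite under a minute while leaving the binomial noise well inside the
acceptance bands.

## Limitations

Beyond the generator's idealizations: no empirical-Bayes scores
(MGPS/EBGM) or full Bayesian BCPNN posterior; no multiple-comparison
control across PTs (screening practice applies none, but thousands of PTs
mean many chance flags); no record linkage beyond exact case-id
deduplication; no MedDRA hierarchy traversal (PTs are compared as
normalized strings); and no ingredient-level drug dictionaries — matching
is string-based and config-driven.
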