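Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for pharmacovigilance signal detection in
    FAERS-style spontaneous adverse event reporting databases. Reads quarterly
    "$"-delimited DEMO/DRUG/REAC extract files in both the legacy (ISR-keyed)
    and modern (primaryid/caseid-keyed) dialects, deduplicates case versions,
    selects cases for a drug of interest with suspect-role filtering, tallies
    MedDRA preferred-term frequencies, and computes disproportionality
    statistics (reporting odds ratio, proportional reporting ratio, chi-squared,
    and the information component) with confidence bounds and a three-way
    signal classification. Includes a synthetic quarterly-file generator with
    analytically known ground-truth drug-event association strengths so the
    whole pipeline is testable without access to the real database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
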