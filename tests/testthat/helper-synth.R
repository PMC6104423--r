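# shared fixture builders: every dataset is generated in code at test time

# a small mixed-era configuration with one planted pair
small_config <- function(n = 500, rate_ratio = 6, duplicate_fraction = 0.1,
                         seed = 7) {
  synth_config(
    n_cases_per_quarter = n,
    quarters = c("2012Q2", "2012Q3", "2012Q4", "2013Q1"),
    drug_vocabulary = c(levonorgestrel = 0.05, ibuprofen = 0.2,
                        metformin = 0.1),
    event_vocabulary = c("Menstruation delayed" = 0.02, "Headache" = 0.1,
                         "Nausea" = 0.08),
    planted_associations = data.frame(
      drug = "levonorgestrel", event = "Menstruation delayed",
      rate_ratio = rate_ratio
    ),
    duplicate_fraction = duplicate_fraction,
    seed = seed
  )
}

# independent brute-force recount used as the oracle for pipeline counts:
# base-R parsing and counting, no faersignal internals
brute_force_counts <- function(dir, drug_substring, roles, pt) {
  read_file <- function(path) {
    utils::read.table(path, sep = "$", header = TRUE, quote = "",
                      comment.char = "", colClasses = "character")
  }
  stems <- sub("^DEMO", "", basename(list.files(dir, pattern = "^DEMO")))
  demo_all <- list(); drug_all <- list(); reac_all <- list()
  for (s in stems) {
    demo <- read_file(file.path(dir, paste0("DEMO", s)))
    drug <- read_file(file.path(dir, paste0("DRUG", s)))
    reac <- read_file(file.path(dir, paste0("REAC", s)))
    if ("ISR" %in% names(demo)) {
      # legacy: key is ISR, case id in DEMO$CASE, version = ISR rank
      ord <- order(demo$CASE, as.numeric(demo$ISR))
      demo <- demo[ord, ]
      ver <- stats::ave(as.numeric(demo$ISR), demo$CASE, FUN = rank)
      demo_all[[s]] <- data.frame(key = demo$ISR, case = demo$CASE,
                                  version = ver)
      map <- setNames(demo$CASE, demo$ISR)
      drug_all[[s]] <- data.frame(case = unname(map[drug$ISR]), key = drug$ISR,
                                  name = drug$DRUGNAME, role = drug$ROLE_COD)
      reac_all[[s]] <- data.frame(case = unname(map[reac$ISR]), key = reac$ISR,
                                  pt = reac$PT)
    } else {
      demo_all[[s]] <- data.frame(key = demo$primaryid, case = demo$caseid,
                                  version = as.numeric(demo$caseversion))
      drug_all[[s]] <- data.frame(case = drug$caseid, key = drug$primaryid,
                                  name = drug$drugname, role = drug$role_cod)
      reac_all[[s]] <- data.frame(case = reac$caseid, key = reac$primaryid,
                                  pt = reac$pt)
    }
  }
  demo <- do.call(rbind, demo_all)
  drug <- do.call(rbind, drug_all)
  reac <- do.call(rbind, reac_all)

  # keep the latest version of each case
  demo <- demo[order(demo$case, demo$version, as.numeric(demo$key)), ]
  latest <- demo[!duplicated(demo$case, fromLast = TRUE), ]
  keep_key <- setNames(latest$key, latest$case)
  drug <- drug[drug$key == keep_key[drug$case], ]
  reac <- reac[reac$key == keep_key[reac$case], ]

  hit <- grepl(drug_substring, tolower(drug$name), fixed = TRUE) &
    drug$role %in% roles
  drug_cases <- unique(drug$case[hit])
  pt_cases <- unique(reac$case[tolower(reac$pt) == tolower(pt)])
  list(
    n = nrow(latest),
    n_j = length(drug_cases),
    n_i = length(pt_cases),
    n_ij = length(intersect(drug_cases, pt_cases)),
    drug_cases = sort(drug_cases)
  )
}
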