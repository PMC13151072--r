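#' Synthetic preferred-term catalogue
#'
#' A stand-in PT -> primary SOC catalogue with per-term background reporting
#' odds, used because MedDRA itself is licensed and cannot be shipped. The
#' 32 terms span 14 SOCs and include the adverse events most relevant to
#' histone deacetylase inhibitor safety profiles (haematotoxicity, cardiac
#' arrhythmia, gastrointestinal toxicity, tumour lysis syndrome,
#' hepatotoxicity, peripheral neuropathy). Background odds are per-report
#' reporting odds of the order seen in spontaneous-report databases
#' (0.1-5% of reports mentioning a given term).
#'
#' @return data frame with columns `pt_name`, `soc_name`,
#'   `background_odds`.
#' @export
default_pt_catalog <- function() {
  df <- utils::read.csv(text = '
pt_name,soc_name,background_odds
Atrial fibrillation,Cardiac disorders,0.004
Cardiac failure,Cardiac disorders,0.005
Electrocardiogram QT prolonged,Cardiac disorders,0.002
Constipation,Gastrointestinal disorders,0.008
Diarrhoea,Gastrointestinal disorders,0.02
Nausea,Gastrointestinal disorders,0.02
Vomiting,Gastrointestinal disorders,0.012
Tumour lysis syndrome,Metabolism and nutrition disorders,0.002
Decreased appetite,Metabolism and nutrition disorders,0.01
Hyponatraemia,Metabolism and nutrition disorders,0.004
Liver disorder,Hepatobiliary disorders,0.006
Hepatic function abnormal,Hepatobiliary disorders,0.01
Neuropathy peripheral,Nervous system disorders,0.004
Dysgeusia,Nervous system disorders,0.003
Headache,Nervous system disorders,0.008
Anaemia,Blood and lymphatic system disorders,0.008
Thrombocytopenia,Blood and lymphatic system disorders,0.01
Neutropenia,Blood and lymphatic system disorders,0.008
Febrile neutropenia,Blood and lymphatic system disorders,0.005
Pyrexia,General disorders and administration site conditions,0.015
Malaise,General disorders and administration site conditions,0.008
Disease progression,General disorders and administration site conditions,0.004
Death,General disorders and administration site conditions,0.006
Platelet count decreased,Investigations,0.012
White blood cell count decreased,Investigations,0.01
Alanine aminotransferase increased,Investigations,0.012
Pneumonia,Infections and infestations,0.012
Sepsis,Infections and infestations,0.005
Herpes zoster,Infections and infestations,0.003
Hypersensitivity,Immune system disorders,0.004
Malignant neoplasm progression,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",0.003
Cataract,Eye disorders,0.002
Vision blurred,Eye disorders,0.002
Rash,Skin and subcutaneous tissue disorders,0.015
Interstitial lung disease,"Respiratory, thoracic and mediastinal disorders",0.008
Dyspnoea,"Respiratory, thoracic and mediastinal disorders",0.006
Acute kidney injury,Renal and urinary disorders,0.006
Myalgia,Musculoskeletal and connective tissue disorders,0.004
', stringsAsFactors = FALSE)
  df
}

#' Term map derived from a synthetic PT catalogue
#'
#' @param catalog data frame with `pt_name` and `soc_name` columns, as from
#'   [default_pt_catalog()].
#' @param version_label label recorded on the map.
#' @return a [term_map()].
#' @export
catalog_term_map <- function(catalog, version_label = "synthetic") {
  term_map(catalog$pt_name, catalog$soc_name, version_label = version_label)
}

#' Default demographic distributions for synthetic reports
#'
#' Categorical sampling weights shaped like the study populations of
#' oncology drugs in a national spontaneous-report database: elderly-skewed
#' ages (about two thirds of reports aged 70 or over), a modest male excess,
#' and physicians as the dominant reporter type.
#'
#' @return named list of named weight vectors (`sex`, `age`,
#'   `reporter_type`), each summing to 1.
#' @export
default_demographics <- function() {
  list(
    sex = c(male = 0.619, female = 0.356, unknown = 0.025),
    age = c("30s" = 0.020, "40s" = 0.040, "50s" = 0.100, "60s" = 0.165,
            "70s" = 0.400, "80s" = 0.220, "90s" = 0.027, unknown = 0.028),
    reporter_type = c(physician = 0.876, pharmacist = 0.071,
                      other_health_professional = 0.028,
                      consumer = 0.003, others = 0.022))
}

#' Configuration for the synthetic report-database generator
#'
#' The defaults describe the study conditions the package is validated
#' against: an index drug on the market from April 2018 with 323 reports, a
#' comparator launched mid-2021 with 753 reports (so the two drugs have
#' unequal reporting windows), a background of 997,321 reports for other
#' drugs (998,397 reports in total), and an extraction window of April 2018
#' to July 2025.
#'
#' Planted effects multiply the background odds of a (drug, PT) pair by
#' `target_ror`, which makes the population head-to-head reporting odds
#' ratio for that term exactly `target_ror` — the property the parameter
#' recovery tests rely on.
#'
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @param n_background_cases number of reports for background drugs.
#' @param index_drug,comparator_drug lists with `name`, `n_cases`,
#'   `launch_date` (`"YYYY-MM"`).
#' @param pt_catalog data frame `pt_name`, `soc_name`, `background_odds`.
#' @param planted_effects data frame `drug_name`, `pt_name`, `target_ror`
#'   (possibly empty; pairs must be unique).
#' @param demographics list of weight vectors as in
#'   [default_demographics()]; each must sum to 1 within 1e-9.
#' @param period reporting window, named character vector
#'   `c(start = "YYYY-MM", end = "YYYY-MM")`.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_background_cases = 997321L,
    index_drug = list(name = "romidepsin", n_cases = 323L,
                      launch_date = "2018-04"),
    comparator_drug = list(name = "tucidinostat", n_cases = 753L,
                           launch_date = "2021-06"),
    pt_catalog = default_pt_catalog(),
    planted_effects = data.frame(drug_name = character(0),
                                 pt_name = character(0),
                                 target_ror = numeric(0)),
    demographics = default_demographics(),
    period = c(start = "2018-04", end = "2025-07")) {

  stopifnot(is.numeric(seed), length(seed) == 1)
  for (nm in c("sex", "age", "reporter_type")) {
    w <- demographics[[nm]]
    if (is.null(w) || is.null(names(w)) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-9)
      stop("config error: demographics$", nm,
           " must be named non-negative weights summing to 1", call. = FALSE)
  }
  if (any(pt_catalog$background_odds <= 0))
    stop("config error: background_odds must be positive", call. = FALSE)
  if (nrow(planted_effects)) {
    if (any(planted_effects$target_ror <= 0))
      stop("config error: target_ror must be positive", call. = FALSE)
    key <- paste(normalize_term(planted_effects$drug_name),
                 normalize_term(planted_effects$pt_name))
    if (anyDuplicated(key))
      stop("config error: planted (drug, pt) pairs must be unique",
           call. = FALSE)
  }
  if (is.na(ym_index(period[["start"]])) || is.na(ym_index(period[["end"]])) ||
      ym_index(period[["start"]]) > ym_index(period[["end"]]))
    stop("config error: invalid reporting period", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_background_cases = as.integer(n_background_cases),
                 index_drug = index_drug, comparator_drug = comparator_drug,
                 pt_catalog = pt_catalog, planted_effects = planted_effects,
                 demographics = demographics, period = period),
            class = "synthetic_config")
}

planted_multiplier <- function(config, drug, pts) {
  mult <- rep(1, length(pts))
  pe <- config$planted_effects
  if (nrow(pe)) {
    pe_drug <- pe[normalize_term(pe$drug_name) == normalize_term(drug), , drop = FALSE]
    if (nrow(pe_drug)) {
      i <- match(normalize_term(pts), normalize_term(pe_drug$pt_name))
      mult[!is.na(i)] <- pe_drug$target_ror[i[!is.na(i)]]
    }
  }
  mult
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws a complete three-table dataset plus ground truth. Each case's
#' reactions are independent per-term Bernoulli draws with probability
#' `odds / (1 + odds)`, where the odds for a planted (drug, term) pair are
#' `background_odds * target_ror` (so a case may report several events, or
#' none). Report dates are uniform over the months between the drug's
#' launch (or the window start, if later) and the window end; demographics
#' are i.i.d. from the configured distributions. Deterministic given
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_dataset`: list with `tables` (data
#'   frames `demo`, `drug`, `reac`), `ground_truth` (per-term odds,
#'   expected counts and true log-RORs) and `config`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  cat_ <- config$pt_catalog
  cohorts <- list(
    index = list(drug = config$index_drug$name,
                 n = config$index_drug$n_cases,
                 launch = config$index_drug$launch_date,
                 prefix = "R", role = "suspected"),
    comparator = list(drug = config$comparator_drug$name,
                      n = config$comparator_drug$n_cases,
                      launch = config$comparator_drug$launch_date,
                      prefix = "T", role = "suspected"),
    background = list(drug = NA, n = config$n_background_cases,
                      launch = config$period[["start"]],
                      prefix = "B", role = "suspected"))

  demo_list <- drug_list <- reac_list <- list()
  truth_rows <- list()
  p_start <- ym_index(config$period[["start"]])
  p_end <- ym_index(config$period[["end"]])

  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    n <- ch$n
    if (n == 0) next
    ids <- sprintf("%s%07d", ch$prefix, seq_len(n))

    mult <- if (nm == "background") rep(1, nrow(cat_)) else
      planted_multiplier(config, ch$drug, cat_$pt_name)
    odds <- cat_$background_odds * mult
    prob <- odds / (1 + odds)

    # per-term Bernoulli draws, column at a time to bound memory
    hit_case <- hit_term <- list()
    for (j in seq_len(nrow(cat_))) {
      hits <- which(stats::runif(n) < prob[j])
      if (length(hits)) {
        hit_case[[length(hit_case) + 1L]] <- ids[hits]
        hit_term[[length(hit_term) + 1L]] <- rep(cat_$pt_name[j], length(hits))
      }
    }
    reac_list[[nm]] <- data.frame(case_id = unlist(hit_case) %||% character(0),
                                  pt_name = unlist(hit_term) %||% character(0),
                                  stringsAsFactors = FALSE)

    months <- max(ym_index(ch$launch), p_start):p_end
    dem <- config$demographics
    demo_list[[nm]] <- data.frame(
      case_id = ids, report_seq = 1L,
      sex = sample(names(dem$sex), n, TRUE, dem$sex),
      age_category = sample(names(dem$age), n, TRUE, dem$age),
      report_date = ym_format(sample(months, n, TRUE)),
      reporter_type = sample(names(dem$reporter_type), n, TRUE,
                             dem$reporter_type),
      stringsAsFactors = FALSE)

    drug_name <- if (nm == "background")
      sprintf("other drug %02d", sample.int(20L, n, TRUE)) else ch$drug
    drug_list[[nm]] <- data.frame(case_id = ids, drug_name = drug_name,
                                  role = ch$role, stringsAsFactors = FALSE)

    truth_rows[[nm]] <- data.frame(cohort = nm, term = cat_$pt_name,
                                   odds = odds, prob = prob,
                                   expected_count = n * prob,
                                   stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  gt <- build_ground_truth(truth, cohorts)
  structure(list(tables = list(demo = do.call(rbind, c(demo_list, list(make.row.names = FALSE))),
                               drug = do.call(rbind, c(drug_list, list(make.row.names = FALSE))),
                               reac = do.call(rbind, c(reac_list, list(make.row.names = FALSE)))),
                 ground_truth = gt, config = config),
            class = "synthetic_dataset")
}

build_ground_truth <- function(truth, cohorts) {
  terms <- unique(truth$term)
  pick <- function(coh, col) {
    i <- match(terms, truth$term[truth$cohort == coh])
    truth[truth$cohort == coh, col][i]
  }
  has_bg <- "background" %in% truth$cohort
  odds_idx <- pick("index", "odds")
  odds_comp <- pick("comparator", "odds")
  exp_idx <- pick("index", "expected_count")
  exp_comp <- pick("comparator", "expected_count")
  # "all other drugs" arm = comparator + background mixture
  n_other <- cohorts$comparator$n + cohorts$background$n
  exp_other <- ifelse(is.na(exp_comp), 0, exp_comp) +
    if (has_bg) pick("background", "expected_count") else 0
  odds_other <- exp_other / (n_other - exp_other)
  data.frame(term = terms,
             odds_index = odds_idx, odds_comparator = odds_comp,
             expected_a_index = exp_idx,
             expected_c_head_to_head = exp_comp,
             expected_c_vs_all = exp_other,
             log_ror_head_to_head = log(odds_idx / odds_comp),
             log_ror_vs_all = log(odds_idx / odds_other),
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Emits `demo.csv`, `drug.csv`, `reac.csv` (loadable with
#' [read_case_tables()] under the default column map), `term_map.csv`
#' (loadable with [load_term_map()]) and `ground_truth.json`. Output is
#' byte-identical for the same generated object.
#'
#' @param x a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv",
                            "term_map.csv", "ground_truth.json"))
  utils::write.csv(x$tables$demo, paths[1], row.names = FALSE)
  utils::write.csv(x$tables$drug, paths[2], row.names = FALSE)
  utils::write.csv(x$tables$reac, paths[3], row.names = FALSE)
  utils::write.csv(data.frame(pt = x$config$pt_catalog$pt_name,
                              soc = x$config$pt_catalog$soc_name),
                   paths[4], row.names = FALSE)
  jsonlite::write_json(x$ground_truth, paths[5], digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

#' Deterministic fixture with exact per-term report counts
#'
#' Builds a two-cohort dataset in which [count_term_reports()] returns
#' exactly the requested `a` (index) and `c` (comparator) for every term —
#' no randomness involved. Terms are assigned to the first `a` index cases
#' and first `c` comparator cases, so different terms overlap on the same
#' cases exactly as spontaneous reports with several coded events do. Used
#' to turn recovered published tables into end-to-end pipeline fixtures.
#'
#' @param counts data frame with columns `term`, `a`, `c`.
#' @param n_index,n_comparator cohort sizes (margins).
#' @param index_drug,comparator_drug drug names carried on the drug rows.
#' @param report_date date stamped on every case.
#' @return list of data frames `demo`, `drug`, `reac` in the default column
#'   layout.
#' @export
fixture_from_tables <- function(counts, n_index, n_comparator,
                                index_drug = "romidepsin",
                                comparator_drug = "tucidinostat",
                                report_date = "2022-01") {
  stopifnot(all(c("term", "a", "c") %in% names(counts)))
  if (any(counts$a > n_index) || any(counts$c > n_comparator) ||
      any(counts$a < 0) || any(counts$c < 0))
    stop("infeasible counts: a must be within [0, n_index] and c within [0, n_comparator]",
         call. = FALSE)
  idx_ids <- sprintf("R%07d", seq_len(n_index))
  comp_ids <- sprintf("T%07d", seq_len(n_comparator))
  demo <- data.frame(case_id = c(idx_ids, comp_ids), report_seq = 1L,
                     sex = "unknown", age_category = "unknown",
                     report_date = report_date, reporter_type = "physician",
                     stringsAsFactors = FALSE)
  drug <- data.frame(case_id = c(idx_ids, comp_ids),
                     drug_name = c(rep(index_drug, n_index),
                                   rep(comparator_drug, n_comparator)),
                     role = "suspected", stringsAsFactors = FALSE)
  reac <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(case_id = c(idx_ids[seq_len(counts$a[i])],
                           comp_ids[seq_len(counts$c[i])]),
               pt_name = counts$term[i], stringsAsFactors = FALSE)
  }))
  if (is.null(reac))
    reac <- data.frame(case_id = idx_ids[1], pt_name = "filler term",
                       stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac)
}

#' Deterministic single-cohort fixture with exact demographic margins
#'
#' Builds a cohort whose [summarize_demographics()] output reproduces the
#' supplied marginal counts exactly. Attributes are assigned independently
#' (category blocks are filled in order), which preserves every marginal
#' total; joint distributions are arbitrary.
#'
#' @param drug_name drug carried by every case.
#' @param sex_counts,age_counts,year_counts,reporter_counts named integer
#'   vectors; all must sum to the same total. `age_counts` uses decade bins
#'   (`"0s"`..`"100s"`, `"unknown"`), `year_counts` is named by year and
#'   dated mid-year.
#' @return list of data frames `demo`, `drug`, `reac`.
#' @export
fixture_demographics_cohort <- function(drug_name, sex_counts, age_counts,
                                        year_counts, reporter_counts) {
  n <- sum(sex_counts)
  if (sum(age_counts) != n || sum(year_counts) != n ||
      sum(reporter_counts) != n)
    stop("marginal counts must all sum to the same cohort size", call. = FALSE)
  ids <- sprintf("C%07d", seq_len(n))
  demo <- data.frame(
    case_id = ids, report_seq = 1L,
    sex = rep(names(sex_counts), sex_counts),
    age_category = rep(names(age_counts), age_counts),
    report_date = rep(paste0(names(year_counts), "-06"), year_counts),
    reporter_type = rep(names(reporter_counts), reporter_counts),
    stringsAsFactors = FALSE)
  drug <- data.frame(case_id = ids, drug_name = drug_name, role = "suspected",
                     stringsAsFactors = FALSE)
  reac <- data.frame(case_id = ids, pt_name = "pyrexia",
                     stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac)
}

#' Write raw three-table fixtures to CSV
#'
#' @param tables list of data frames `demo`, `drug`, `reac` (as from
#'   [fixture_from_tables()] or a `synthetic_dataset`'s `tables`).
#' @param dir output directory.
#' @return invisibly, named paths to the three CSVs.
#' @export
write_case_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(demo = file.path(dir, "demo.csv"),
             drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"))
  utils::write.csv(tables$demo, paths[["demo"]], row.names = FALSE)
  utils::write.csv(tables$drug, paths[["drug"]], row.names = FALSE)
  utils::write.csv(tables$reac, paths[["reac"]], row.names = FALSE)
  invisible(paths)
}
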