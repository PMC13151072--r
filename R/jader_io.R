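#' Default column mapping for JADER-layout case tables
#'
#' Maps the package's field names to the column headers found in the three
#' CSV tables. Real JADER exports use Japanese headers; synthetic fixtures
#' use the English defaults below. Supply a modified mapping to
#' [read_case_tables()] to load either.
#'
#' @return nested named list with elements `demo`, `drug`, `reac`, each a
#'   named character vector `field = column header`.
#' @export
default_column_map <- function() {
  list(
    demo = c(case_id = "case_id", report_seq = "report_seq", sex = "sex",
             age_category = "age_category", report_date = "report_date",
             reporter_type = "reporter_type"),
    drug = c(case_id = "case_id", drug_name = "drug_name", role = "role"),
    reac = c(case_id = "case_id", pt_name = "pt_name")
  )
}

read_one_table <- function(path, map, which, encoding) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = encoding, check.names = FALSE)
  missing <- setdiff(unname(map), names(df))
  if (length(missing))
    stop(sprintf("table '%s' (%s) lacks required column(s): %s",
                 which, path, paste(missing, collapse = ", ")), call. = FALSE)
  out <- df[, unname(map), drop = FALSE]
  names(out) <- names(map)
  out
}

#' Read the three JADER-layout case tables
#'
#' Parses the demographics, drug and reaction CSV tables into raw record
#' frames with columns renamed to the package's field names. Category values
#' that do not parse onto their vocabulary (sex, drug role, reporter type,
#' age decade) become `"unknown"`; they are never dropped. Linkage,
#' deduplication and orphan handling happen afterwards in
#' [link_and_dedup()].
#'
#' @param demo_path,drug_path,reac_path paths to the three CSV tables.
#' @param encoding file encoding, `"UTF-8"` (default, synthetic fixtures) or
#'   `"Shift_JIS"` (real JADER exports).
#' @param column_map column mapping as from [default_column_map()].
#' @return list with data frames `demo`, `drug`, `reac` and a `provenance`
#'   record of the source paths.
#' @seealso [link_and_dedup()], [read_jader()]
#' @export
read_case_tables <- function(demo_path, drug_path, reac_path,
                             encoding = c("UTF-8", "Shift_JIS"),
                             column_map = default_column_map()) {
  encoding <- match.arg(encoding)
  demo <- read_one_table(demo_path, column_map$demo, "demo", encoding)
  drug <- read_one_table(drug_path, column_map$drug, "drug", encoding)
  reac <- read_one_table(reac_path, column_map$reac, "reac", encoding)

  demo$case_id <- trimws(demo$case_id)
  demo$report_seq <- suppressWarnings(as.integer(demo$report_seq))
  demo$report_seq[is.na(demo$report_seq)] <- 1L
  demo$sex <- coerce_enum(demo$sex, .sex_levels)
  demo$age_category <- coerce_enum(demo$age_category, .age_levels)
  demo$report_date <- ym_format(ym_index(demo$report_date))
  demo$reporter_type <- coerce_enum(demo$reporter_type, .reporter_levels)

  drug$case_id <- trimws(drug$case_id)
  drug$drug_name <- normalize_term(drug$drug_name)
  drug$role <- coerce_enum(drug$role, .role_levels)

  reac$case_id <- trimws(reac$case_id)
  reac$pt_name <- normalize_term(reac$pt_name)

  list(demo = demo, drug = drug, reac = reac,
       provenance = list(demo = demo_path, drug = drug_path,
                         reac = reac_path, encoding = encoding))
}

#' Link and deduplicate raw case records into a report dataset
#'
#' Produces the canonical in-memory dataset: one demographic record per case
#' (the highest `report_seq` wins — JADER re-submissions share a case id;
#' ties keep the last row read), drug and reaction rows restricted to cases
#' present in the demographics table (orphans are counted and excluded), and
#' duplicate (case, preferred term) reaction pairs collapsed, so a case can
#' never contribute twice to one term's report count. Rows whose key fields
#' are empty after normalization are dropped and counted.
#'
#' @param raw list as returned by [read_case_tables()].
#' @return an object of class `report_dataset`: list with data frames
#'   `cases` (one row per case), `drugs`, `reactions`, plus `load_report`
#'   (counts of rows read, orphans excluded, versions and duplicates
#'   collapsed) and `provenance`.
#' @export
link_and_dedup <- function(raw) {
  demo <- raw$demo; drug <- raw$drug; reac <- raw$reac

  demo <- demo[!is.na(demo$case_id) & demo$case_id != "", , drop = FALSE]
  n_demo_in <- nrow(demo)
  # keep highest report_seq per case; ties -> last occurrence
  if (nrow(demo)) {
    ord <- order(demo$case_id, demo$report_seq, seq_len(nrow(demo)))
    demo <- demo[ord, , drop = FALSE]
    keep <- !duplicated(demo$case_id, fromLast = TRUE)
    demo <- demo[keep, , drop = FALSE]
    demo <- demo[order(demo$case_id), , drop = FALSE]
  }
  ids <- demo$case_id

  # normalization is idempotent, so raw frames built in memory and frames
  # that already passed through read_case_tables link identically
  drug$drug_name <- normalize_term(drug$drug_name)
  reac$pt_name <- normalize_term(reac$pt_name)

  drop_bad <- function(df, field) {
    ok <- !is.na(df$case_id) & df$case_id != "" & !is.na(df[[field]])
    df[ok, , drop = FALSE]
  }
  drug <- drop_bad(drug, "drug_name")
  reac <- drop_bad(reac, "pt_name")

  orphan_drug <- sum(!(drug$case_id %in% ids))
  orphan_reac <- sum(!(reac$case_id %in% ids))
  drug <- drug[drug$case_id %in% ids, , drop = FALSE]
  reac <- reac[reac$case_id %in% ids, , drop = FALSE]

  drug <- drug[!duplicated(drug[c("case_id", "drug_name", "role")]), , drop = FALSE]
  n_reac_in <- nrow(reac)
  reac <- reac[!duplicated(reac[c("case_id", "pt_name")]), , drop = FALSE]

  rownames(demo) <- rownames(drug) <- rownames(reac) <- NULL
  structure(
    list(cases = demo, drugs = drug, reactions = reac,
         load_report = list(
           n_demo_rows = n_demo_in, n_cases = nrow(demo),
           n_versions_dropped = n_demo_in - nrow(demo),
           n_orphan_drug = orphan_drug, n_orphan_reac = orphan_reac,
           n_duplicate_reactions = n_reac_in - nrow(reac)),
         provenance = raw$provenance),
    class = "report_dataset")
}

#' Read, link and deduplicate in one call
#'
#' @inheritParams read_case_tables
#' @return a `report_dataset`; see [link_and_dedup()].
#' @export
read_jader <- function(demo_path, drug_path, reac_path,
                       encoding = c("UTF-8", "Shift_JIS"),
                       column_map = default_column_map()) {
  link_and_dedup(read_case_tables(demo_path, drug_path, reac_path,
                                  encoding = encoding, column_map = column_map))
}

#' @export
print.report_dataset <- function(x, ...) {
  cat("report_dataset:", nrow(x$cases), "cases,",
      nrow(x$drugs), "drug rows,", nrow(x$reactions), "reaction rows\n")
  lr <- x$load_report
  cat(sprintf("  load report: %d demo rows read, %d versions dropped, %d orphan drug / %d orphan reaction rows excluded, %d duplicate reactions collapsed\n",
              lr$n_demo_rows, lr$n_versions_dropped, lr$n_orphan_drug,
              lr$n_orphan_reac, lr$n_duplicate_reactions))
  invisible(x)
}

#' Restrict a report dataset to a reporting window
#'
#' Keeps cases whose report date falls inside the closed interval
#' `[start, end]` at year-month precision, pruning linked drug and reaction
#' rows. JADER supplies partial dates, so cases with an unknown report date
#' are retained by default (and counted in the load report); set
#' `strict = TRUE` to exclude them.
#'
#' @param dataset a `report_dataset`.
#' @param start,end window bounds as `"YYYY-MM"` strings (both inclusive).
#' @param strict if `TRUE`, cases with unknown dates are excluded.
#' @return a filtered `report_dataset`.
#' @export
filter_period <- function(dataset, start, end, strict = FALSE) {
  stopifnot(inherits(dataset, "report_dataset"))
  s <- ym_index(start); e <- ym_index(end)
  if (is.na(s) || is.na(e))
    stop("start and end must be parseable 'YYYY-MM' dates", call. = FALSE)
  if (s > e) stop("inverted period: start is after end", call. = FALSE)
  d <- ym_index(dataset$cases$report_date)
  keep <- !is.na(d) & d >= s & d <= e
  if (!strict) keep <- keep | is.na(d)
  cases <- dataset$cases[keep, , drop = FALSE]
  ids <- cases$case_id
  out <- dataset
  out$cases <- cases
  out$drugs <- dataset$drugs[dataset$drugs$case_id %in% ids, , drop = FALSE]
  out$reactions <- dataset$reactions[dataset$reactions$case_id %in% ids, , drop = FALSE]
  out$load_report$n_cases <- nrow(cases)
  out$load_report$n_outside_period <-
    (out$load_report$n_outside_period %||% 0L) + sum(!keep)
  out$load_report$n_unknown_date_kept <- if (strict) 0L else sum(is.na(d) & keep)
  out$provenance$period <- c(start = ym_format(s), end = ym_format(e))
  rownames(out$cases) <- rownames(out$drugs) <- rownames(out$reactions) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
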