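#' Specify a drug cohort
#'
#' A case belongs to the cohort when any of its drug rows matches any of the
#' synonyms (exact match on normalized names) and passes the role filter.
#' The default `any_role` counts a drug however it was reported; spontaneous
#' report analyses sometimes restrict to suspected drugs, which
#' `suspected_only` provides.
#'
#' @param drug_query character vector of drug-name synonyms (at least one).
#' @param role_filter `"any_role"` (default) or `"suspected_only"`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(drug_query, role_filter = c("any_role", "suspected_only")) {
  role_filter <- match.arg(role_filter)
  drug_query <- normalize_term(drug_query)
  drug_query <- unique(drug_query[!is.na(drug_query)])
  if (!length(drug_query))
    stop("cohort_spec needs at least one non-empty drug synonym", call. = FALSE)
  structure(list(drug_query = drug_query, role_filter = role_filter),
            class = "cohort_spec")
}

#' Specify the comparator arm
#'
#' Two designs: `all_other_drugs` (classical disproportionality — the
#' comparator is every case not in the index cohort) and `head_to_head`
#' (the comparator is another named drug's cohort; cases reporting both
#' drugs are excluded from both arms so the 2x2 margins stay disjoint).
#'
#' @param mode `"all_other_drugs"` or `"head_to_head"`.
#' @param cohort a [cohort_spec()] for the comparator drug; required for
#'   head-to-head, ignored otherwise.
#' @return object of class `comparator_spec`.
#' @export
comparator_spec <- function(mode = c("all_other_drugs", "head_to_head"),
                            cohort = NULL) {
  mode <- match.arg(mode)
  if (mode == "head_to_head" && !inherits(cohort, "cohort_spec"))
    stop("head_to_head mode requires a comparator cohort_spec", call. = FALSE)
  structure(list(mode = mode,
                 cohort = if (mode == "head_to_head") cohort),
            class = "comparator_spec")
}

#' Select the case ids forming a cohort
#'
#' @param dataset a `report_dataset`.
#' @param spec a [cohort_spec()].
#' @return character vector of case ids (sorted, unique); empty with a
#'   warning when no case matches.
#' @export
select_cohort <- function(dataset, spec) {
  stopifnot(inherits(dataset, "report_dataset"), inherits(spec, "cohort_spec"))
  d <- dataset$drugs
  hit <- d$drug_name %in% spec$drug_query
  if (spec$role_filter == "suspected_only") hit <- hit & d$role == "suspected"
  ids <- sort(unique(d$case_id[hit]))
  if (!length(ids))
    warning("cohort query matched no cases: ",
            paste(spec$drug_query, collapse = ", "), call. = FALSE)
  ids
}

#' Count reports per term within a cohort
#'
#' The counting unit is the report (case): a case contributes at most one to
#' a term's count no matter how many of its reactions resolve to the term,
#' but may contribute to several different terms. At SOC level each PT is
#' first resolved through the term map; unmapped PTs are dropped with a
#' warning.
#'
#' @param dataset a `report_dataset`.
#' @param cohort character vector of case ids.
#' @param level `"pt"` or `"soc"`.
#' @param term_map a [term_map()]; required for `level = "soc"`.
#' @return named integer vector, term -> number of distinct reports.
#' @export
count_term_reports <- function(dataset, cohort, level = c("pt", "soc"),
                               term_map = NULL) {
  level <- match.arg(level)
  r <- dataset$reactions
  r <- r[r$case_id %in% cohort, , drop = FALSE]
  term <- r$pt_name
  if (level == "soc") {
    if (!inherits(term_map, "term_map"))
      stop("SOC-level counting requires a term_map", call. = FALSE)
    term <- map_pt(term_map, term)
    if (anyNA(term)) {
      warning(sum(is.na(term)), " reaction row(s) with unmapped PT excluded ",
              "from SOC-level counts", call. = FALSE)
      r <- r[!is.na(term), , drop = FALSE]
      term <- term[!is.na(term)]
    }
  }
  if (!nrow(r)) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(data.frame(case_id = r$case_id, term = term,
                             stringsAsFactors = FALSE))
  tab <- table(pairs$term)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a 2x2 report-count contingency table
#'
#' Cell `a` counts index-cohort reports mentioning the term, `b` those that
#' do not (so `a + b` is the index cohort size); `c` and `d` are the same
#' for the comparator. In `all_other_drugs` mode the comparator is every
#' case outside the index cohort; in `head_to_head` mode cases in both
#' cohorts are excluded from both arms.
#'
#' @param dataset a `report_dataset`.
#' @param index_spec a [cohort_spec()] for the index drug.
#' @param comparator a [comparator_spec()].
#' @param term the term to tabulate (PT or SOC name, any case).
#' @param level `"pt"` or `"soc"`.
#' @param term_map required for SOC level.
#' @return a `contingency_table`; see [contingency_table()].
#' @export
build_contingency <- function(dataset, index_spec, comparator, term,
                              level = c("pt", "soc"), term_map = NULL) {
  level <- match.arg(level)
  arms <- resolve_arms(dataset, index_spec, comparator)
  term <- normalize_term(term)
  a <- count_in(dataset, arms$index, term, level, term_map)
  c_ <- count_in(dataset, arms$comparator, term, level, term_map)
  contingency_table(a, length(arms$index) - a,
                    c_, length(arms$comparator) - c_,
                    term = term, level = level)
}

resolve_arms <- function(dataset, index_spec, comparator) {
  stopifnot(inherits(comparator, "comparator_spec"))
  idx <- select_cohort(dataset, index_spec)
  if (comparator$mode == "all_other_drugs") {
    comp <- setdiff(dataset$cases$case_id, idx)
    overlap <- character(0)
  } else {
    comp <- select_cohort(dataset, comparator$cohort)
    overlap <- intersect(idx, comp)
    if (length(overlap))
      message(length(overlap),
              " case(s) report both drugs; excluded from both arms")
    idx <- setdiff(idx, overlap)
    comp <- setdiff(comp, overlap)
  }
  list(index = idx, comparator = sort(comp), overlap = overlap)
}

count_in <- function(dataset, cohort, term, level, term_map) {
  counts <- count_term_reports(dataset, cohort, level, term_map)
  if (term %in% names(counts)) counts[[term]] else 0L
}

#' Construct a contingency table of report counts
#'
#' @param a,b,c,d non-negative integer cell counts: `a`/`b` index reports
#'   with/without the term, `c`/`d` comparator reports with/without it.
#' @param term term label.
#' @param level `"pt"` or `"soc"`.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, term = "", level = c("pt", "soc")) {
  level <- match.arg(level)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), term = term, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table [%s] '%s': a=%d b=%d c=%d d=%d (index n=%d, comparator n=%d)\n",
              x$level, x$term, x$a, x$b, x$c, x$d, x$a + x$b, x$c + x$d))
  invisible(x)
}

#' Summarize cohort demographics
#'
#' Reproduces the usual "study population" table of spontaneous-report
#' analyses: counts and percentages by age (`<70`, `>=70`, unknown, from the
#' decade bins), sex, reporting year and reporter type. Percentages are
#' rounded half-up to one decimal.
#'
#' @param dataset a `report_dataset`.
#' @param cohort character vector of case ids (non-empty).
#' @return a data frame with columns `block`, `category`, `n`, `pct` and
#'   attribute `total`.
#' @export
summarize_demographics <- function(dataset, cohort) {
  stopifnot(inherits(dataset, "report_dataset"))
  cases <- dataset$cases[dataset$cases$case_id %in% cohort, , drop = FALSE]
  n <- nrow(cases)
  if (!n) stop("cannot summarize an empty cohort", call. = FALSE)

  age_group <- ifelse(cases$age_category == "unknown", "unknown",
               ifelse(cases$age_category %in% paste0(7:10 * 10, "s"),
                      ">=70", "<70"))
  yr <- ym_year(cases$report_date)
  year_group <- ifelse(is.na(yr), "unknown", as.character(yr))

  block <- function(name, values, levels) {
    tab <- table(factor(values, levels = levels))
    data.frame(block = name, category = names(tab), n = as.integer(tab),
               pct = round_half_up(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }
  year_levels <- as.character(sort(unique(yr)))
  if (any(is.na(yr))) year_levels <- c(year_levels, "unknown")
  out <- rbind(
    block("age", age_group, c("<70", ">=70", "unknown")),
    block("sex", cases$sex, c("male", "female", "unknown")),
    block("reporting_year", year_group, year_levels),
    block("reporter_type", cases$reporter_type,
          c(.reporter_levels, "unknown")))
  # drop all-zero "unknown" filler rows so blocks mirror the data
  out <- out[!(out$category == "unknown" & out$n == 0L), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- n
  out
}
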