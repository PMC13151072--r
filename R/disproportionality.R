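#' Haldane-Anscombe continuity correction
#'
#' When any cell of the 2x2 table is zero the odds ratio or its log-scale
#' variance is undefined; the classical remedy adds 0.5 to all four cells.
#' The correction is conditional: tables with all cells positive are left
#' untouched, which is what reproduces published estimates computed on
#' uncorrected tables.
#'
#' @param table a [contingency_table()].
#' @return list with `cells` (numeric a, b, c, d, possibly +0.5) and
#'   `corrected` (logical).
#' @export
apply_continuity_correction <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  corrected <- min(cells) == 0
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' The disproportionality statistic of spontaneous-report analysis: for a
#' table with `a`/`b` index reports with/without the event and `c`/`d`
#' comparator reports,
#' \deqn{ROR = \frac{a/b}{c/d}, \quad
#'       SE(\ln ROR) = \sqrt{1/a + 1/b + 1/c + 1/d},}
#' with the CI `exp(ln ROR +/- z * SE)`. Zero cells are handled by the
#' conditional Haldane-Anscombe correction
#' ([apply_continuity_correction()]). Because no exposure denominators
#' exist in these databases, the ROR describes reporting patterns, not
#' incidence or risk.
#'
#' @param table a [contingency_table()].
#' @param conf_z normal quantile for the interval; default `1.959964`
#'   (97.5th percentile, a 95% CI).
#' @return object of class `ror_estimate`: list with `ror`, `ci_low`,
#'   `ci_high`, `se_log`, `corrected`, `fisher_p` (`NA` until filled by the
#'   caller) and `cells_used`. Full precision is kept; rounding half-up to
#'   2 decimals is applied only when tables are written out.
#' @export
#' @examples
#' compute_ror(contingency_table(11, 312, 1, 752))
compute_ror <- function(table, conf_z = 1.959964) {
  cc <- apply_continuity_correction(table)
  k <- cc$cells
  if (all(c(table$a, table$b, table$c, table$d) == 0))
    stop("undefined estimate: empty contingency table", call. = FALSE)
  ror <- (k[["a"]] / k[["b"]]) / (k[["c"]] / k[["d"]])
  se <- sqrt(sum(1 / k))
  structure(list(ror = ror,
                 ci_low = exp(log(ror) - conf_z * se),
                 ci_high = exp(log(ror) + conf_z * se),
                 se_log = se, corrected = cc$corrected,
                 fisher_p = NA_real_, cells_used = k),
            class = "ror_estimate")
}

#' @export
print.ror_estimate <- function(x, ...) {
  cat(sprintf("ROR %s [%s-%s]%s%s\n",
              format(round_half_up(x$ror, 2), nsmall = 2),
              format(round_half_up(x$ci_low, 2), nsmall = 2),
              format(round_half_up(x$ci_high, 2), nsmall = 2),
              if (x$corrected) ", Haldane-Anscombe corrected" else "",
              if (!is.na(x$fisher_p))
                sprintf(", Fisher p = %.4g", x$fisher_p) else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact at any table size: the two-sided p-value is the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the observed table's probability (with a
#' relative tolerance of 1e-7 for floating-point ties). The support of the
#' hypergeometric distribution is enumerated in full — no normal or
#' chi-square approximation at large margins.
#'
#' @param table a [contingency_table()] (integer cells; the correction is
#'   never applied here).
#' @return p-value in (0, 1]. Degenerate margins (an empty row or column)
#'   return 1 by convention, with a message.
#' @export
#' @examples
#' fisher_exact_two_sided(contingency_table(3, 0, 0, 3))  # 0.1
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    message("degenerate margins in Fisher test; p = 1 by convention")
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  p_all <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
}

#' Minimum-case rule for screening
#'
#' A term is tested only when either arm has more than `threshold` reported
#' cases (strict inequality): sparse terms produce unstable estimates and
#' are reported as not tested rather than silently dropped.
#'
#' @param table a [contingency_table()].
#' @param threshold minimum case count; default 3 ("more than three cases").
#' @return logical: should the term be tested?
#' @export
min_case_rule <- function(table, threshold = 3) {
  stopifnot(inherits(table, "contingency_table"))
  table$a > threshold || table$c > threshold
}

#' Classify a screened estimate as a signal
#'
#' EudraVigilance-style thresholds. Against all other drugs, a signal for
#' the index drug needs ROR > 1 with the lower 95% bound above 1. In a
#' head-to-head comparison the criterion is symmetric: a CI entirely above
#' 1 flags the index drug, entirely below 1 flags the comparator.
#'
#' @param estimate a `ror_estimate`.
#' @param mode `"all_other_drugs"` or `"head_to_head"`.
#' @return one of `"index_signal"`, `"comparator_signal"`, `"none"`.
#' @export
classify_signal <- function(estimate, mode = c("all_other_drugs", "head_to_head")) {
  mode <- match.arg(mode)
  stopifnot(inherits(estimate, "ror_estimate"))
  if (estimate$ror > 1 && estimate$ci_low > 1) return("index_signal")
  if (mode == "head_to_head" && estimate$ror < 1 && estimate$ci_high < 1)
    return("comparator_signal")
  "none"
}

#' Screen every observed term for disproportionality
#'
#' The full per-term pipeline: resolve the index and comparator arms, count
#' reports for every term observed in either arm (PT level, or SOC level
#' through the term map), apply the minimum-case rule, and for tested terms
#' compute the ROR with its 95% CI (conditional Haldane-Anscombe
#' correction), the exact Fisher p-value on the integer cells, and the
#' signal classification. Results are sorted by descending ROR among tested
#' terms (ties, and all untested terms, ordered by term name) and are fully
#' deterministic given the inputs.
#'
#' @param dataset a `report_dataset`.
#' @param index_spec a [cohort_spec()].
#' @param comparator a [comparator_spec()].
#' @param level `"pt"` or `"soc"`.
#' @param term_map required at SOC level.
#' @param min_cases minimum-case threshold (strict; default 3).
#' @param conf_z normal quantile of the CI (default 1.959964).
#' @return data frame of class `signal_screen` with one row per term:
#'   `term`, `level`, `mode`, `a`, `b`, `c`, `d`, `corrected`, `ror`,
#'   `ci_low`, `ci_high`, `se_log`, `fisher_p`, `tested`, `signal`.
#'   Untested terms carry `NA` estimates and signal `"not_tested"`.
#' @export
run_screen <- function(dataset, index_spec, comparator,
                       level = c("pt", "soc"), term_map = NULL,
                       min_cases = 3, conf_z = 1.959964) {
  level <- match.arg(level)
  arms <- resolve_arms(dataset, index_spec, comparator)
  n_idx <- length(arms$index); n_comp <- length(arms$comparator)
  cnt_idx <- count_term_reports(dataset, arms$index, level, term_map)
  cnt_comp <- count_term_reports(dataset, arms$comparator, level, term_map)
  terms <- sort(union(names(cnt_idx), names(cnt_comp)))

  rows <- lapply(terms, function(tm) {
    a <- if (tm %in% names(cnt_idx)) cnt_idx[[tm]] else 0L
    c_ <- if (tm %in% names(cnt_comp)) cnt_comp[[tm]] else 0L
    tab <- contingency_table(a, n_idx - a, c_, n_comp - c_,
                             term = tm, level = level)
    # an empty arm leaves nothing to compare, whatever the other arm counts
    tested <- n_idx > 0 && n_comp > 0 && min_case_rule(tab, threshold = min_cases)
    if (tested) {
      est <- compute_ror(tab, conf_z = conf_z)
      p <- fisher_exact_two_sided(tab)
      sig <- classify_signal(est, comparator$mode)
      data.frame(term = tm, level = level, mode = comparator$mode,
                 a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 corrected = est$corrected, ror = est$ror,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 se_log = est$se_log, fisher_p = p,
                 tested = TRUE, signal = sig, stringsAsFactors = FALSE)
    } else {
      data.frame(term = tm, level = level, mode = comparator$mode,
                 a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 corrected = NA, ror = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 se_log = NA_real_, fisher_p = NA_real_,
                 tested = FALSE, signal = "not_tested",
                 stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(term = character(0), level = character(0),
                      mode = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), corrected = logical(0),
                      ror = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), se_log = numeric(0),
                      fisher_p = numeric(0), tested = logical(0),
                      signal = character(0), stringsAsFactors = FALSE)
  }
  ord <- order(!out$tested, -ifelse(is.na(out$ror), -Inf, out$ror), out$term)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_index") <- n_idx
  attr(out, "n_comparator") <- n_comp
  attr(out, "n_overlap_excluded") <- length(arms$overlap)
  class(out) <- c("signal_screen", "data.frame")
  out
}
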