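#' Recover integer contingency tables from a published estimate
#'
#' Published disproportionality results print a rounded ROR and 95% CI but
#' rarely the underlying cell counts. Given the printed values and the two
#' cohort sizes (which usually are printed), this oracle searches integer
#' `(a, c)` pairs whose recomputed estimate, rounded half-up to 2 decimals,
#' matches the printed values on the requested fields — turning published
#' results back into exact tables. The search is exhaustive over the stated
#' space, with no heuristics: soundness and completeness are what make the
#' recovered tables usable as test fixtures.
#'
#' For small comparator margins the full `(n_index+1) x (n_comparator+1)`
#' grid is scanned. For database-scale margins the `c` range scanned for
#' each `a` is derived deterministically by inverting the point estimate at
#' the edges of its rounding interval (widened by the slack and a fixed
#' +/-5 count guard), which covers every `c` that could round to the
#' printed point estimate.
#'
#' @param ror,ci_low,ci_high printed values (2 decimals).
#' @param n_index,n_comparator cohort sizes (`a + b` and `c + d`).
#' @param match which printed fields must match; any subset of
#'   `c("point", "ci_low", "ci_high")`.
#' @param slack tolerance in units of the last printed decimal (0.01);
#'   default 0 (exact). `slack = 1` accommodates software that rounds the
#'   last digit differently.
#' @param conf_z normal quantile used to recompute the CI.
#' @param grid_limit largest full grid scanned before switching to the
#'   windowed search.
#' @return data frame of candidates: `a`, `c`, and the recomputed `ror`,
#'   `ci_low`, `ci_high` (full precision), sorted by `a` then `c`. Zero
#'   rows when no integer table matches.
#' @export
#' @examples
#' recover_table(7.17, 1.93, 26.64, 323, 753)  # unique: a = 9, c = 3
recover_table <- function(ror, ci_low, ci_high, n_index, n_comparator,
                          match = c("point", "ci_low", "ci_high"),
                          slack = 0, conf_z = 1.959964, grid_limit = 4e6) {
  match <- match.arg(match, several.ok = TRUE)
  stopifnot(n_index >= 1, n_comparator >= 1)
  if ((n_index + 1) * (n_comparator + 1) <= grid_limit) {
    grid <- expand.grid(a = 0:n_index, c = 0:n_comparator)
  } else {
    tol <- 0.005 + slack * 0.01 + 1e-9
    grid <- do.call(rbind, lapply(0:n_index, function(a) {
      if (a == 0) return(data.frame(a = 0L, c = 0:min(n_comparator, 50L)))
      # corrected odds at the b = 0 edge so the window stays finite
      odds <- if (a == n_index) (a + 0.5) / 0.5 else a / (n_index - a)
      # c solving (a/b)/(c/d) = r for the rounding-interval edges of r
      c_at <- function(r) odds * n_comparator / (r + odds)
      lo <- max(0L, floor(c_at(ror + tol)) - 5L)
      hi <- min(n_comparator, ceiling(c_at(max(ror - tol, 1e-12))) + 5L)
      data.frame(a = a, c = unique(c(0:min(n_comparator, 5L), lo:hi)))
    }))
  }
  est <- ror_vectorized(grid$a, n_index - grid$a, grid$c,
                        n_comparator - grid$c, conf_z)
  ok <- rep(TRUE, nrow(grid))
  tol <- slack * 0.01 + 1e-9
  if ("point" %in% match)
    ok <- ok & !is.na(est$ror) & abs(round_half_up(est$ror, 2) - ror) <= tol
  if ("ci_low" %in% match)
    ok <- ok & !is.na(est$ci_low) & abs(round_half_up(est$ci_low, 2) - ci_low) <= tol
  if ("ci_high" %in% match)
    ok <- ok & !is.na(est$ci_high) & abs(round_half_up(est$ci_high, 2) - ci_high) <= tol
  out <- data.frame(a = grid$a[ok], c = grid$c[ok], ror = est$ror[ok],
                    ci_low = est$ci_low[ok], ci_high = est$ci_high[ok])
  out <- out[order(out$a, out$c), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Vectorized ROR/CI with the conditional Haldane-Anscombe correction;
# internal workhorse for the recovery grid.
ror_vectorized <- function(a, b, c, d, conf_z = 1.959964) {
  corr <- pmin(a, b, c, d) == 0
  a2 <- a + 0.5 * corr; b2 <- b + 0.5 * corr
  c2 <- c + 0.5 * corr; d2 <- d + 0.5 * corr
  ror <- (a2 / b2) / (c2 / d2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  bad <- (a + b) == 0 | (c + d) == 0
  ror[bad] <- NA_real_
  list(ror = ror,
       ci_low = exp(log(ror) - conf_z * se),
       ci_high = exp(log(ror) + conf_z * se),
       corrected = corr)
}

#' Verify one candidate table against printed values
#'
#' @param a,c candidate cell counts for the index and comparator arms.
#' @inheritParams recover_table
#' @return list with `ok` (logical) and `estimate` (the recomputed
#'   `ror_estimate`).
#' @export
#' @examples
#' verify_candidate(18, 2, 22.16, 5.11, 96.09, 323, 753)$ok  # TRUE
verify_candidate <- function(a, c, ror, ci_low, ci_high,
                             n_index, n_comparator,
                             match = c("point", "ci_low", "ci_high"),
                             slack = 0, conf_z = 1.959964) {
  match <- match.arg(match, several.ok = TRUE)
  est <- compute_ror(contingency_table(a, n_index - a, c, n_comparator - c),
                     conf_z = conf_z)
  tol <- slack * 0.01 + 1e-9
  ok <- TRUE
  if ("point" %in% match)
    ok <- ok && abs(round_half_up(est$ror, 2) - ror) <= tol
  if ("ci_low" %in% match)
    ok <- ok && abs(round_half_up(est$ci_low, 2) - ci_low) <= tol
  if ("ci_high" %in% match)
    ok <- ok && abs(round_half_up(est$ci_high, 2) - ci_high) <= tol
  list(ok = ok, estimate = est)
}
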