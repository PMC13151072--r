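#' Normalize a term or drug name
#'
#' Applies Unicode NFKC normalization, trims surrounding whitespace and
#' case-folds to lower case. All matching in the package (drug synonyms,
#' preferred terms, SOC names) happens on normalized strings, so
#' `"ATRIAL FIBRILLATION"` and `"Atrial fibrillation"` are the same term.
#'
#' @param x character vector.
#' @return character vector of the same length; `NA` stays `NA`, and strings
#'   that are empty after trimming become `NA`.
#' @export
#' @examples
#' normalize_term(c("  Atrial Fibrillation ", "PYREXIA"))
normalize_term <- function(x) {
  x <- as.character(x)
  out <- stringi::stri_trans_nfkc(x)
  out <- stringi::stri_trim_both(out)
  out <- stringi::stri_trans_tolower(out)
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported estimates and
#' percentages, as opposed to [round()]'s round-half-to-even. A tiny epsilon
#' guards against binary representation error just below a half boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.675, 2)  # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Year-month handling: report dates carry year-month precision ("YYYY-MM").
# Internally a month index (year * 12 + month - 1); NA for unknown/unparseable.
ym_index <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^\\s*([0-9]{4})[-/]?([0-9]{1,2})\\s*$", x))
  vapply(m, function(g) {
    if (length(g) < 3) return(NA_real_)
    yr <- as.numeric(g[2]); mo <- as.numeric(g[3])
    if (is.na(yr) || is.na(mo) || mo < 1 || mo > 12) return(NA_real_)
    yr * 12 + mo - 1
  }, numeric(1))
}

ym_format <- function(idx) {
  ifelse(is.na(idx), NA_character_,
         sprintf("%04d-%02d", idx %/% 12, idx %% 12 + 1))
}

ym_year <- function(x) {
  idx <- ym_index(x)
  ifelse(is.na(idx), NA_integer_, as.integer(idx %/% 12))
}

# Coerce a raw category value onto a closed vocabulary; anything not matching
# (after normalization) maps to "unknown" rather than failing.
coerce_enum <- function(x, levels) {
  v <- normalize_term(x)
  v[is.na(v) | !(v %in% levels)] <- "unknown"
  v
}

.sex_levels <- c("male", "female")
.role_levels <- c("suspected", "concomitant", "interacting")
.reporter_levels <- c("physician", "pharmacist", "other_health_professional",
                      "consumer", "others")
.age_levels <- paste0(0:10 * 10, "s")
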