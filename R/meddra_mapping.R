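#' Construct a preferred-term to system-organ-class map
#'
#' Each MedDRA preferred term (PT) has exactly one primary system organ
#' class (SOC); SOC-level report counting relies on that uniqueness. Keys
#' and values are normalized with [normalize_term()], so lookups are
#' case-insensitive. MedDRA content is licensed and is not shipped with the
#' package: supply your own extract, or use the synthetic catalogue from
#' [default_pt_catalog()] for testing.
#'
#' @param pt,soc character vectors of equal length.
#' @param version_label free-text label of the dictionary version.
#' @return an object of class `term_map`.
#' @export
term_map <- function(pt, soc, version_label = "unversioned") {
  pt <- normalize_term(pt); soc <- normalize_term(soc)
  ok <- !is.na(pt) & !is.na(soc)
  pt <- pt[ok]; soc <- soc[ok]
  dup <- duplicated(paste(pt, soc, sep = "\r"))
  pt <- pt[!dup]; soc <- soc[!dup]
  conflict <- unique(pt[duplicated(pt)])
  if (length(conflict))
    stop("PT mapped to more than one primary SOC: ",
         paste(conflict, collapse = ", "), call. = FALSE)
  structure(stats::setNames(soc, pt), class = "term_map",
            version_label = version_label)
}

#' Load a PT to primary-SOC mapping table from CSV
#'
#' Expects a UTF-8 CSV with columns `pt` and `soc`. Duplicate identical rows
#' collapse; the same PT mapped to two different SOCs is a mapping conflict
#' and an error.
#'
#' @param path CSV path.
#' @param version_label optional dictionary version label.
#' @return a `term_map`.
#' @export
load_term_map <- function(path, version_label = basename(path)) {
  if (!file.exists(path)) stop("term map file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("pt", "soc"), names(df))
  if (length(missing))
    stop("term map lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  term_map(df$pt, df$soc, version_label = version_label)
}

#' Resolve preferred terms to their primary SOC
#'
#' Total and deterministic: every input gets either its unique primary SOC
#' or `NA` (unmapped). Unmapped PTs are excluded from SOC-level screens with
#' a warning (real exports contain coding lags) but are kept in PT-level
#' screens.
#'
#' @param map a `term_map`.
#' @param pt_name character vector of preferred terms (any case).
#' @return character vector of SOC names, `NA` where unmapped.
#' @export
#' @examples
#' tm <- term_map("Atrial fibrillation", "Cardiac disorders")
#' map_pt(tm, c("ATRIAL FIBRILLATION", "xyzzy"))
map_pt <- function(map, pt_name) {
  stopifnot(inherits(map, "term_map"))
  unname(unclass(map)[normalize_term(pt_name)])
}

#' @export
print.term_map <- function(x, ...) {
  cat("term_map:", length(x), "PTs ->", length(unique(unclass(x))),
      "SOCs (", attr(x, "version_label"), ")\n")
  invisible(x)
}
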