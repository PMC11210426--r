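#' Read a country indicator table
#'
#' Reads a CSV of country records (one row per country/survey) into a
#' validated \code{country_table}. Required columns: a country id, a
#' country name, annual births and the EBF/PBF and partial prevalences;
#' optional: survey source and non-breastfed prevalence. Columns are
#' resolved through a configurable name mapping, numbers may carry
#' thousands separators, and empty prevalence cells mark a "no data"
#' row. Rows that fail validation are retained and flagged rather than
#' aborting the read; per-row diagnostics are attached.
#'
#' @param path path to a CSV file (header required, UTF-8).
#' @param col_map named character vector mapping canonical names
#'   (\code{id}, \code{name}, \code{source}, \code{births},
#'   \code{ebf_pbf}, \code{partial}, \code{non_bf}) to the file's column
#'   names; defaults to the canonical names themselves.
#' @return an object of class \code{country_table}: a data frame with
#'   canonical columns plus logical \code{no_data} and \code{valid} and
#'   character \code{reason}; attribute \code{"diagnostics"} holds a
#'   data frame of (row, reason) for flagged rows.
#' @export
read_country_table <- function(path, col_map = NULL) {
  defaults <- c(id = "id", name = "name", source = "source",
                births = "births", ebf_pbf = "ebf_pbf",
                partial = "partial", non_bf = "non_bf")
  map <- defaults
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("id", "name", "births", "ebf_pbf", "partial")
  missing_cols <- map[required][!map[required] %in% names(raw)]
  if (length(missing_cols))
    stop_validation("missing required column(s): ",
                    paste(missing_cols, collapse = ", "))
  get <- function(key) {
    if (map[[key]] %in% names(raw)) raw[[map[[key]]]]
    else rep(NA_character_, nrow(raw))
  }
  tab <- data.frame(id = get("id"), name = get("name"),
                    source = ifelse(is.na(get("source")), "", get("source")),
                    births = parse_number(get("births")),
                    ebf_pbf = parse_number(get("ebf_pbf")),
                    partial = parse_number(get("partial")),
                    non_bf = parse_number(get("non_bf")),
                    stringsAsFactors = FALSE)
  .validate_country_table(tab)
}

.validate_country_table <- function(tab) {
  n <- nrow(tab)
  tab$no_data <- is.na(tab$ebf_pbf) & is.na(tab$partial) & is.na(tab$non_bf)
  tab$valid <- rep(TRUE, n)
  tab$reason <- rep("", n)
  if (anyDuplicated(tab$id)) {
    dup <- unique(tab$id[duplicated(tab$id)])
    stop_validation("duplicate country id(s): ", paste(dup, collapse = ", "))
  }
  for (i in seq_len(n)) {
    if (is.na(tab$births[i])) {
      tab$valid[i] <- FALSE
      tab$reason[i] <- "unparseable or missing births"
      next
    }
    if (tab$no_data[i]) next
    res <- tryCatch(
      feeding_prevalence(tab$ebf_pbf[i], tab$partial[i], tab$non_bf[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      tab$valid[i] <- FALSE
      tab$reason[i] <- conditionMessage(res)
    } else {
      tab$non_bf[i] <- res[["non_bf"]]
    }
  }
  diag <- data.frame(row = which(!tab$valid), reason = tab$reason[!tab$valid],
                     stringsAsFactors = FALSE)
  structure(tab, diagnostics = diag, class = c("country_table", "data.frame"))
}

#' Diagnostics collected while reading a country table
#'
#' @param tab a \code{country_table}.
#' @return data frame with columns \code{row} and \code{reason} for every
#'   flagged row (zero rows when the table is clean).
#' @export
table_diagnostics <- function(tab) {
  stopifnot(inherits(tab, "country_table"))
  attr(tab, "diagnostics")
}

#' Turn a country-table row into a cohort
#'
#' @param tab a \code{country_table}.
#' @param id country id to look up.
#' @return a \code{\link{cohort_spec}}.
#' @export
cohort_from_table <- function(tab, id) {
  stopifnot(inherits(tab, "country_table"))
  i <- match(id, tab$id)
  if (is.na(i)) {
    near <- tab$id[agrepl(id, tab$id, ignore.case = TRUE, max.distance = 0.3)]
    stop_validation("unknown country id '", id, "'",
                    if (length(near)) paste0("; near matches: ",
                                             paste(near, collapse = ", "))
                    else "")
  }
  if (tab$no_data[i])
    stop_validation("country '", id, "' has no preloaded prevalence data; ",
                    "enter own data instead")
  if (!tab$valid[i])
    stop_validation("country '", id, "' row is invalid: ", tab$reason[i])
  cohort_spec(label = tab$name[i], annual_births = tab$births[i],
              prevalence = feeding_prevalence(tab$ebf_pbf[i], tab$partial[i],
                                              tab$non_bf[i]),
              source = tab$source[i])
}

#' Write footprint results to a file
#'
#' Serializes a list of footprint results and/or scenario comparisons.
#' The delimited (CSV) layout mirrors the published tables: label,
#' births, prevalence shares, lost milk, carbon low, carbon high, water
#' (plus raw CMF kg); numbers are written at full precision with no
#' thousands separators so the file round-trips exactly. The structured
#' format is JSON with the same fields.
#'
#' @param results a non-empty list of \code{footprint_result} and/or
#'   \code{scenario_comparison} objects (a single object is accepted).
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(results, c("footprint_result", "scenario_comparison")))
    results <- list(results)
  if (!is.list(results) || length(results) == 0L)
    stop_validation("nothing to write: results list is empty")
  frames <- lapply(results, function(r) {
    if (!inherits(r, c("footprint_result", "scenario_comparison")))
      stop_validation("results must be footprint_result or scenario_comparison objects")
    as.data.frame(r)
  })
  df <- do.call(rbind, frames)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(df, path, digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back results written by \code{write_results}
#'
#' @param path file written by \code{\link{write_results}}.
#' @param format \code{"csv"} or \code{"json"}.
#' @return data frame of result rows (full stored precision).
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
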