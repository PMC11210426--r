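#' Round half away from zero
#'
#' Display rounding used everywhere in the package. Survey tables and
#' published footprint figures round 0.5 up (e.g. 15,204.75 prints as
#' 15,204.8), whereas base R's \code{round()} rounds half to even.
#' Internal arithmetic is never rounded; this routine is applied only at
#' the reporting boundary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the precision used
#'   in published country tables).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(15204.75)   # 15204.8
#' round_half_up(0.25, 1)    # 0.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Parse numbers that may carry thousands separators ("11,501,936") or be
# empty / dashes (no-data markers). Returns NA for unparseable input.
parse_number <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "-", "–", "—", "NA")] <- NA_character_
  suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
}

# Format a number for human-readable reports: big marks, fixed decimals.
fmt_num <- function(x, digits = 1) {
  ifelse(is.na(x), "–",
         formatC(round_half_up(x, digits), format = "f",
                 digits = digits, big.mark = ","))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
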