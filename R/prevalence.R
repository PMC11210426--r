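#' Feeding-practice prevalence of infants under 6 months
#'
#' Represents the shares of infants under 6 months in the three mutually
#' exclusive feeding categories used by the calculator: exclusively or
#' predominantly breastfed (\code{ebf_pbf}), partially breastfed
#' (\code{partial}, mixed feeding), and non-breastfed (\code{non_bf},
#' fully formula-fed). Percentages are handled on the 0--100 scale
#' throughout; they are converted to fractions only inside arithmetic.
#'
#' Exactly one category may be omitted (\code{NA}); it is completed as
#' the complement so the three shares sum to 100. This mirrors own-data
#' entry from surveys that report only exclusive and partial rates. A
#' derived complement between -0.1 and 0 (survey rounding) is clamped to
#' zero; a more negative complement is treated as a data-entry error.
#'
#' @param ebf_pbf percentage exclusively or predominantly breastfed.
#' @param partial percentage partially breastfed.
#' @param non_bf percentage non-breastfed; defaults to the complement.
#' @return an object of class \code{feeding_prevalence}: a named numeric
#'   vector with components \code{ebf_pbf}, \code{partial}, \code{non_bf}
#'   summing to 100 within 0.1 percentage points.
#' @export
#' @examples
#' feeding_prevalence(61.3, 32.2)          # non_bf completed as 6.5
#' feeding_prevalence(90, 8, 2)
feeding_prevalence <- function(ebf_pbf = NA_real_, partial = NA_real_,
                               non_bf = NA_real_) {
  v <- c(ebf_pbf = as.numeric(ebf_pbf), partial = as.numeric(partial),
         non_bf = as.numeric(non_bf))
  supplied <- !is.na(v)
  if (sum(supplied) < 2L)
    stop_validation("at least two of ebf_pbf, partial, non_bf must be supplied")
  if (any(v[supplied] < 0))
    stop_validation("negative prevalence supplied: ",
                    paste(sprintf("%s=%g", names(v)[supplied & v < 0],
                                  v[supplied & v < 0]), collapse = ", "))
  if (any(v[supplied] > 100))
    stop_validation("prevalence above 100 supplied: ",
                    paste(sprintf("%s=%g", names(v)[supplied & v > 100],
                                  v[supplied & v > 100]), collapse = ", "))
  s <- sum(v[supplied])
  if (sum(supplied) == 2L) {
    if (s > 100.1)
      stop_validation("supplied prevalences sum to ", s,
                      " > 100; cannot derive the missing category")
    comp <- 100 - s
    if (comp < -0.1)
      stop_validation("derived complement ", comp, " below -0.1")
    v[!supplied] <- max(comp, 0)
  } else {
    if (abs(s - 100) > 0.1)
      stop_validation("prevalences sum to ", s,
                      ", not 100 within 0.1 percentage points")
  }
  structure(v, class = "feeding_prevalence")
}

#' Complete and validate a partial prevalence record
#'
#' Normalizes a raw record (named list/vector with any of \code{ebf_pbf},
#' \code{partial}, \code{non_bf}, missing entries as \code{NA} or absent)
#' into a complete \code{\link{feeding_prevalence}}. Idempotent on
#' already-complete records.
#'
#' @param raw a \code{feeding_prevalence}, named numeric vector or list.
#' @return a \code{feeding_prevalence}.
#' @export
normalize_prevalence <- function(raw) {
  if (inherits(raw, "feeding_prevalence")) raw <- unclass(raw)
  raw <- as.list(raw)
  feeding_prevalence(ebf_pbf = raw$ebf_pbf %||% NA_real_,
                     partial = raw$partial %||% NA_real_,
                     non_bf = raw$non_bf %||% NA_real_)
}

#' @export
print.feeding_prevalence <- function(x, ...) {
  cat(sprintf("Feeding prevalence (<6 months): EBF/PBF %.1f%%, partial %.1f%%, non-breastfed %.1f%%\n",
              x[["ebf_pbf"]], x[["partial"]], x[["non_bf"]]))
  invisible(x)
}

.bands <- c("0-1", "2-3", "4-5")

#' Prevalence for one age band
#'
#' Pairs a two-month age band with its feeding prevalence. Band-level
#' survey data uses the bands 0--1, 2--3 and 4--5 months.
#'
#' @param band one of \code{"0-1"}, \code{"2-3"}, \code{"4-5"} (months).
#' @param prevalence a \code{\link{feeding_prevalence}} or coercible record.
#' @return an object of class \code{age_band_prevalence}.
#' @export
age_band_prevalence <- function(band, prevalence) {
  band <- as.character(band)
  if (!band %in% .bands)
    stop_validation("band must be one of ", paste(.bands, collapse = ", "),
                    " (got '", band, "')")
  structure(list(band = band, prevalence = normalize_prevalence(prevalence)),
            class = "age_band_prevalence")
}

#' Aggregate age-band prevalences to an under-6-months prevalence
#'
#' Takes the unweighted arithmetic mean of each feeding category across
#' the three age bands (the three bands span equal two-month intervals,
#' so the unweighted mean is the under-6-months share under a uniform
#' age distribution).
#'
#' @param bands a list of exactly three \code{\link{age_band_prevalence}}
#'   objects, one per band.
#' @return a \code{\link{feeding_prevalence}}.
#' @export
#' @examples
#' b <- list(age_band_prevalence("0-1", c(ebf_pbf = 90, partial = 10, non_bf = 0)),
#'           age_band_prevalence("2-3", c(ebf_pbf = 60, partial = 30, non_bf = 10)),
#'           age_band_prevalence("4-5", c(ebf_pbf = 30, partial = 50, non_bf = 20)))
#' aggregate_bands(b)   # (60, 30, 10)
aggregate_bands <- function(bands) {
  if (!is.list(bands) || length(bands) != 3L ||
      !all(vapply(bands, inherits, logical(1), "age_band_prevalence")))
    stop_validation("bands must be a list of exactly three age_band_prevalence objects")
  got <- vapply(bands, function(b) b$band, character(1))
  if (anyDuplicated(got) || !setequal(got, .bands))
    stop_validation("bands must cover 0-1, 2-3 and 4-5 months exactly once (got ",
                    paste(got, collapse = ", "), ")")
  m <- colMeans(do.call(rbind, lapply(bands, function(b) unclass(b$prevalence))))
  feeding_prevalence(m[["ebf_pbf"]], m[["partial"]], m[["non_bf"]])
}

#' A population cohort to evaluate
#'
#' A cohort is a population of infants under 6 months described by its
#' annual number of live births and its feeding-practice prevalence
#' (aggregate, band-level, or both). The annual birth count is used
#' directly as the size of the under-6-months population, which is the
#' convention required to reproduce the published country tables.
#'
#' @param label free-text cohort label (country, survey, scenario name).
#' @param annual_births annual live births (>= 0).
#' @param prevalence aggregate \code{\link{feeding_prevalence}} (or a
#'   record coercible to one); may be omitted when \code{bands} is given.
#' @param bands optional list of three \code{\link{age_band_prevalence}};
#'   if \code{prevalence} is also given the two must agree (aggregate
#'   equals the unweighted band mean within 0.5 percentage points).
#' @param source free-text provenance (survey name/year); may be empty.
#' @return an object of class \code{cohort_spec}.
#' @export
#' @examples
#' cohort_spec("China 2018", 11501936, feeding_prevalence(61.3, 32.2))
cohort_spec <- function(label, annual_births, prevalence = NULL,
                        bands = NULL, source = "") {
  annual_births <- as.numeric(annual_births)
  if (length(annual_births) != 1L || is.na(annual_births) || annual_births < 0)
    stop_validation("annual_births must be a single non-negative number")
  if (is.null(prevalence) && is.null(bands))
    stop_validation("supply aggregate prevalence, age-band prevalence, or both")
  if (!is.null(prevalence)) prevalence <- normalize_prevalence(prevalence)
  if (!is.null(bands)) {
    band_mean <- aggregate_bands(bands)
    if (is.null(prevalence)) {
      prevalence <- band_mean
    } else if (max(abs(unclass(prevalence) - unclass(band_mean))) > 0.5) {
      stop_validation("aggregate prevalence disagrees with the unweighted band mean ",
                      "by more than 0.5 percentage points")
    }
  }
  structure(list(label = as.character(label), annual_births = annual_births,
                 prevalence = prevalence, bands = bands,
                 source = as.character(source)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort: %s%s\n", x$label,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  cat(sprintf("  Annual live births: %s\n", fmt_num(x$annual_births, 0)))
  print(x$prevalence)
  if (!is.null(x$bands)) cat("  (band-level prevalence present)\n")
  invisible(x)
}
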