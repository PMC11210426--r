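#' Reference cohorts with published footprints
#'
#' The four cohorts whose inputs and outputs appear in published country
#' tables, usable as known-answer checks: the China 2018 own-data
#' cohort, the Canada before/after-2008 maternity-leave cohorts, and the
#' pooled LMIC cohort evaluated under the extinction scenario.
#'
#' @return named list of \code{\link{cohort_spec}} objects.
#' @export
#' @examples
#' compute_footprint(reference_cohorts()$china_2018)
reference_cohorts <- function() {
  list(
    china_2018 = cohort_spec("China 2018", 11501936,
                             feeding_prevalence(61.3, 32.2),
                             source = "national survey 2018"),
    canada_before_2008 = cohort_spec("Canada before 2008", 373864,
                                     feeding_prevalence(23.1, 51.3),
                                     source = "pre-2008 survey"),
    canada_after_2008 = cohort_spec("Canada after 2008", 373864,
                                    feeding_prevalence(31.5, 45.7),
                                    source = "post-2008 survey"),
    lmic_pooled = cohort_spec("LMIC pooled", 131386401,
                              feeding_prevalence(0, 0, 100),
                              source = "extinction scenario input")
  )
}

#' Generate a synthetic country table
#'
#' Deterministic, seeded generator of UNICEF-IYCF-style country tables
#' for testing and demonstration. Births are drawn log-uniformly between
#' 1e4 and 3e7 (spanning small states to the most populous countries);
#' prevalence triplets are drawn from a Dirichlet distribution (via
#' normalized gamma draws) weighted toward breastfeeding-majority
#' profiles, rounded to 1 decimal as surveys report them and
#' renormalized; a configurable fraction of rows is emitted with empty
#' prevalence cells ("no data", mirroring the dash convention of
#' published tables). The four published reference cohorts are always
#' appended verbatim as known-answer rows.
#'
#' @param n_countries number of synthetic rows (>= 1), excluding the
#'   reference rows.
#' @param seed integer seed; same (n, seed, config) gives the same table.
#' @param no_data_frac fraction of synthetic rows emitted as "no data".
#' @param dirichlet_alpha length-3 concentration for (ebf_pbf, partial,
#'   non_bf); the default favours realistic breastfeeding-majority mixes.
#' @return a \code{country_table}.
#' @export
#' @examples
#' generate_fixtures(5, seed = 42)
generate_fixtures <- function(n_countries, seed,
                              no_data_frac = 0.1,
                              dirichlet_alpha = c(5, 3, 1)) {
  if (!is.numeric(n_countries) || n_countries < 1)
    stop_validation("n_countries must be >= 1")
  n <- as.integer(n_countries)
  stopifnot(length(dirichlet_alpha) == 3L, all(dirichlet_alpha > 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  births <- round(exp(stats::runif(n, log(1e4), log(3e7))))
  g <- matrix(stats::rgamma(3L * n, shape = rep(dirichlet_alpha, each = n)),
              nrow = n)
  shares <- g / rowSums(g) * 100
  shares <- round_half_up(shares, 1)
  # renormalize rounding drift into the largest share
  drift <- 100 - rowSums(shares)
  imax <- max.col(shares)
  shares[cbind(seq_len(n), imax)] <- shares[cbind(seq_len(n), imax)] + drift
  shares <- round_half_up(shares, 1)
  nodata <- stats::runif(n) < no_data_frac

  syn <- data.frame(
    id = sprintf("SYN%03d", seq_len(n)),
    name = sprintf("Synthetic country %d", seq_len(n)),
    source = sprintf("synthetic survey (seed %d)", as.integer(seed)),
    births = births,
    ebf_pbf = ifelse(nodata, NA_real_, shares[, 1]),
    partial = ifelse(nodata, NA_real_, shares[, 2]),
    non_bf = ifelse(nodata, NA_real_, shares[, 3]),
    stringsAsFactors = FALSE)

  refs <- reference_cohorts()
  ref <- data.frame(
    id = c("CHN2018", "CANPRE", "CANPOST", "LMIC"),
    name = vapply(refs, function(x) x$label, character(1)),
    source = vapply(refs, function(x) x$source, character(1)),
    births = vapply(refs, function(x) x$annual_births, numeric(1)),
    ebf_pbf = vapply(refs, function(x) x$prevalence[["ebf_pbf"]], numeric(1)),
    partial = vapply(refs, function(x) x$prevalence[["partial"]], numeric(1)),
    non_bf = vapply(refs, function(x) x$prevalence[["non_bf"]], numeric(1)),
    stringsAsFactors = FALSE)
  rownames(ref) <- NULL
  .validate_country_table(rbind(syn, ref))
}

# Save/restore the RNG state so fixture generation does not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a country table to CSV
#'
#' Canonical header (\code{id,name,source,births,ebf_pbf,partial,non_bf});
#' "no data" prevalences are written as empty cells; no thousands
#' separators, so \code{\link{read_country_table}} round-trips exactly.
#'
#' @param tab a \code{country_table}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_country_table <- function(tab, path) {
  stopifnot(inherits(tab, "country_table"))
  cols <- c("id", "name", "source", "births", "ebf_pbf", "partial", "non_bf")
  utils::write.csv(as.data.frame(tab)[, cols], path, row.names = FALSE,
                   na = "", quote = TRUE)
  invisible(path)
}
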