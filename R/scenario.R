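#' A feeding scenario
#'
#' Wraps a cohort with a description and an intervention coverage
#' fraction (the share of births reached by the intervention).
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @param description free text.
#' @param coverage fraction of births affected, in (0, 1]; default 1.
#' @return an object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(cohort, description = cohort$label, coverage = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
      coverage <= 0 || coverage > 1)
    stop_validation("coverage must be in (0, 1]")
  structure(list(cohort = cohort, description = as.character(description),
                 coverage = coverage),
            class = "scenario_spec")
}

#' Compare a baseline against a counterfactual scenario
#'
#' Computes both footprints and their signed differences (counterfactual
#' minus baseline). A negative difference is an avoided emission or
#' avoided water use; in carbon-offset terms the (negative of the) GHG
#' difference is the additionality of the intervention.
#'
#' @param baseline,counterfactual \code{\link{scenario_spec}} objects or
#'   bare \code{\link{cohort_spec}} objects (coverage 1 assumed).
#' @param params a \code{\link{footprint_params}}.
#' @return an object of class \code{scenario_comparison}: list with
#'   \code{baseline} and \code{counterfactual} footprint results, a
#'   \code{difference} list of signed deltas over the footprint fields,
#'   and \code{prevalence_delta} (percentage-point changes per category).
#' @export
#' @examples
#' base <- cohort_spec("China 2018", 11501936, feeding_prevalence(61.3, 32.2))
#' cf   <- cohort_spec("China counterfactual", 11501936, feeding_prevalence(90, 8))
#' compare_scenarios(base, cf)
compare_scenarios <- function(baseline, counterfactual,
                              params = footprint_params()) {
  as_scen <- function(x) if (inherits(x, "cohort_spec")) scenario_spec(x) else x
  baseline <- as_scen(baseline); counterfactual <- as_scen(counterfactual)
  stopifnot(inherits(baseline, "scenario_spec"),
            inherits(counterfactual, "scenario_spec"))
  if (baseline$cohort$annual_births != counterfactual$cohort$annual_births)
    warning("baseline and counterfactual cohorts have different annual births; ",
            "differences mix population sizes", call. = FALSE)
  b <- compute_footprint(baseline$cohort, params)
  cf <- compute_footprint(counterfactual$cohort, params)
  diff <- stats::setNames(
    lapply(.fp_fields, function(f) cf[[f]] - b[[f]]), .fp_fields)
  structure(list(baseline = b, counterfactual = cf, difference = diff,
                 prevalence_delta = unclass(cf$prevalence) - unclass(b$prevalence),
                 params = params),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  rows <- rbind(.fp_row(x$baseline), .fp_row(x$counterfactual),
                c("Difference", "", sprintf("%+.1f", round_half_up(x$prevalence_delta[["ebf_pbf"]])),
                  sprintf("%+.1f", round_half_up(x$prevalence_delta[["partial"]])),
                  fmt_num(x$difference$lost_milk), fmt_num(x$difference$ghg_low),
                  fmt_num(x$difference$ghg_high), fmt_num(x$difference$water)))
  colnames(rows) <- c("Scenario", "Births", "EBF/PBF %", "Partial %",
                      "Lost milk", "Carbon low", "Carbon high", "Water")
  cat("Baseline vs counterfactual (carbon and water in millions)\n")
  print.default(rows, quote = FALSE, right = TRUE)
  invisible(x)
}

.fp_row <- function(r) {
  c(r$label, fmt_num(r$births, 0),
    fmt_num(r$prevalence[["ebf_pbf"]]), fmt_num(r$prevalence[["partial"]]),
    fmt_num(r$lost_milk), fmt_num(r$ghg_low), fmt_num(r$ghg_high),
    fmt_num(r$water))
}

#' @export
as.data.frame.scenario_comparison <- function(x, ...) {
  b <- as.data.frame(x$baseline); cf <- as.data.frame(x$counterfactual)
  d <- b; d$label <- "Difference"
  d$births <- NA_real_
  for (f in c("ebf_pbf", "partial", "non_bf"))
    d[[f]] <- cf[[f]] - b[[f]]
  for (f in .fp_fields) d[[f]] <- x$difference[[f]]
  rbind(b, cf, d)
}

#' Raise the exclusive/predominant breastfeeding rate
#'
#' Applies a percentage-point uplift to the EBF/PBF share and
#' redistributes the remainder by the two-thirds rule used for
#' intervention scenarios: partial breastfeeding is set to two thirds of
#' the non-EBF/PBF share and non-breastfeeding to one third.
#'
#' @param base a normalized \code{\link{feeding_prevalence}}.
#' @param ebf_increase uplift in percentage points (>= 0).
#' @return a \code{\link{feeding_prevalence}}.
#' @export
#' @examples
#' apply_uplift(feeding_prevalence(58.2, 29.9), 10)   # (68.2, 21.2, 10.6)
apply_uplift <- function(base, ebf_increase) {
  base <- normalize_prevalence(base)
  if (!is.numeric(ebf_increase) || length(ebf_increase) != 1L ||
      is.na(ebf_increase) || ebf_increase < 0)
    stop_validation("ebf_increase must be a single non-negative number")
  ebf <- base[["ebf_pbf"]] + ebf_increase
  if (ebf > 100)
    stop_validation("uplift pushes EBF/PBF to ", ebf, " > 100")
  rest <- 100 - ebf
  feeding_prevalence(ebf, 2 / 3 * rest, 1 / 3 * rest)
}

#' Scale a scenario footprint to an intervention's coverage
#'
#' Reports the footprint of the covered subpopulation under the
#' scenario's feeding rates: every footprint field and the birth count
#' are multiplied by the coverage fraction. (This is the footprint of
#' the covered births at scenario rates, not the covered share of a
#' baseline-to-scenario difference; see
#' \code{\link{avoided_footprint}} for the latter.)
#'
#' @param scenario_result a \code{\link{compute_footprint}} result at
#'   full coverage.
#' @param coverage fraction in (0, 1].
#' @return a \code{footprint_result} for the covered subpopulation, with
#'   \code{births} scaled to the covered birth count.
#' @export
#' @examples
#' indo <- cohort_spec("Indonesia +15pt", 4435250,
#'                     apply_uplift(feeding_prevalence(58.2, 29.9), 15))
#' scale_coverage(compute_footprint(indo), 0.05)
scale_coverage <- function(scenario_result, coverage) {
  stopifnot(inherits(scenario_result, "footprint_result"))
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
      coverage <= 0 || coverage > 1)
    stop_validation("coverage must be in (0, 1]")
  out <- scenario_result
  out$births <- scenario_result$births * coverage
  for (f in .fp_fields) out[[f]] <- scenario_result[[f]] * coverage
  out$label <- sprintf("%s (coverage %g%%)", scenario_result$label,
                       coverage * 100)
  out
}

#' Avoided footprint of a partially covered intervention
#'
#' The coverage-scaled signed difference: for each footprint field,
#' coverage times (counterfactual minus baseline). Negative values are
#' avoided emissions/water.
#'
#' @param comparison a \code{\link{compare_scenarios}} result.
#' @param coverage fraction in (0, 1].
#' @return named list of signed deltas over the footprint fields.
#' @export
avoided_footprint <- function(comparison, coverage = 1) {
  stopifnot(inherits(comparison, "scenario_comparison"))
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
      coverage <= 0 || coverage > 1)
    stop_validation("coverage must be in (0, 1]")
  lapply(comparison$difference, function(v) v * coverage)
}

#' Breastfeeding-extinction scenario
#'
#' Returns the same cohort with all breastfeeding displaced by formula
#' feeding: prevalence (0, 0, 100). Idempotent.
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @return a \code{\link{cohort_spec}} with 100\% non-breastfed prevalence.
#' @export
extinction_scenario <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  cohort_spec(label = paste0(cohort$label, " (extinction)"),
              annual_births = cohort$annual_births,
              prevalence = feeding_prevalence(0, 0, 100),
              source = cohort$source)
}

#' Read scenario definitions from a config file
#'
#' Loads a YAML or JSON scenario configuration. Recognised keys per
#' scenario: \code{label}, \code{births}, \code{prevalence} (mapping
#' with \code{ebf_pbf}/\code{partial}/optional \code{non_bf}) or
#' \code{uplift} (percentage points, applied to the baseline prevalence
#' with the two-thirds rule), \code{coverage} (fraction, default 1),
#' \code{diet} (mapping with \code{pattern} and \code{mothers}). The
#' top level holds \code{baseline} and \code{counterfactual} entries.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a list with \code{baseline} and \code{counterfactual}
#'   \code{\link{scenario_spec}} objects and an optional \code{diet}
#'   list (\code{pattern}, \code{mothers}).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$baseline) || is.null(cfg$counterfactual))
    stop_validation("config must define 'baseline' and 'counterfactual'")
  base_prev <- .cfg_prevalence(cfg$baseline, NULL, "baseline")
  births <- parse_number(cfg$baseline$births %||%
                         cfg$counterfactual$births %||% NA)
  if (is.na(births)) stop_validation("config must give 'births'")
  mk <- function(entry, prev, default_label) {
    scenario_spec(
      cohort_spec(entry$label %||% default_label,
                  parse_number(entry$births %||% births), prev),
      coverage = entry$coverage %||% 1)
  }
  out <- list(
    baseline = mk(cfg$baseline, base_prev, "baseline"),
    counterfactual = mk(cfg$counterfactual,
                        .cfg_prevalence(cfg$counterfactual, base_prev,
                                        "counterfactual"),
                        "counterfactual"))
  if (!is.null(cfg$diet)) {
    if (is.null(cfg$diet$pattern) || is.null(cfg$diet$mothers))
      stop_validation("'diet' needs 'pattern' and 'mothers'")
    out$diet <- list(pattern = cfg$diet$pattern,
                     mothers = parse_number(cfg$diet$mothers))
  }
  out
}

.cfg_prevalence <- function(entry, base_prev, what) {
  if (!is.null(entry$prevalence)) {
    pv <- entry$prevalence
    feeding_prevalence(pv$ebf_pbf %||% NA_real_, pv$partial %||% NA_real_,
                       pv$non_bf %||% NA_real_)
  } else if (!is.null(entry$uplift)) {
    if (is.null(base_prev))
      stop_validation("'uplift' requires a baseline prevalence")
    apply_uplift(base_prev, as.numeric(entry$uplift))
  } else {
    stop_validation("scenario '", what, "' needs 'prevalence' or 'uplift'")
  }
}
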