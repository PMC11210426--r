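#' Annual commercial milk formula requirement of a cohort
#'
#' Closed-form CMF powder mass: each partially breastfed infant consumes
#' \code{m_partial} kg over 6 months and each non-breastfed infant
#' \code{m_full} kg, so
#' \deqn{CMF = births \times (partial/100 \times m_{partial} +
#'       non_{bf}/100 \times m_{full}).}
#' Exclusively/predominantly breastfed infants consume none.
#'
#' @param cohort a \code{\link{cohort_spec}}.
#' @param params a \code{\link{footprint_params}}.
#' @return kg of CMF powder per year (raw kg, not millions).
#' @export
#' @examples
#' canada <- cohort_spec("Canada before 2008", 373864,
#'                       feeding_prevalence(23.1, 51.3))
#' cmf_requirement(canada)   # about 3.2 million kg
cmf_requirement <- function(cohort, params = footprint_params()) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(params, "footprint_params"))
  p <- cohort$prevalence
  cohort$annual_births * (p[["partial"]] / 100 * params$m_partial +
                          p[["non_bf"]] / 100 * params$m_full)
}

#' Greenhouse-gas emission range of a CMF mass
#'
#' Multiplies the annual CMF powder mass by the lower and upper lifecycle
#' emission factors (defaults 11 and 14 kg CO2e per kg powder).
#'
#' @param cmf_kg kg of CMF powder per year.
#' @param params a \code{\link{footprint_params}}.
#' @return named numeric vector \code{c(ghg_low, ghg_high)} in million kg
#'   CO2e per year.
#' @export
ghg_range <- function(cmf_kg, params = footprint_params()) {
  if (!is.numeric(cmf_kg) || length(cmf_kg) != 1L || is.na(cmf_kg) || cmf_kg < 0)
    stop_validation("cmf_kg must be a single non-negative number")
  c(ghg_low = cmf_kg * params$e_low, ghg_high = cmf_kg * params$e_high) / 1e6
}

#' Water footprint of a CMF mass
#'
#' Multiplies the annual CMF powder mass by the operative water intensity
#' (production plus preparation; default 4,752.7 L per kg powder).
#'
#' @inheritParams ghg_range
#' @return million liters of water per year.
#' @export
water_use <- function(cmf_kg, params = footprint_params()) {
  if (!is.numeric(cmf_kg) || length(cmf_kg) != 1L || is.na(cmf_kg) || cmf_kg < 0)
    stop_validation("cmf_kg must be a single non-negative number")
  cmf_kg * params$w_intensity / 1e6
}

#' Lost breastmilk of a cohort
#'
#' Volume of breastmilk not produced because infants are partially or
#' fully formula-fed:
#' \deqn{lost = births \times (non_{bf}/100 + \alpha_{partial} \times
#'       partial/100) \times v_{milk},}
#' with \code{v_milk} liters per fully non-breastfed infant over 6 months
#' and fraction \code{alpha_partial} attributed to each partially
#' breastfed infant.
#'
#' @inheritParams cmf_requirement
#' @return million liters of lost milk per year.
#' @export
lost_milk <- function(cohort, params = footprint_params()) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(params, "footprint_params"))
  p <- cohort$prevalence
  cohort$annual_births *
    (p[["non_bf"]] / 100 + params$alpha_partial * p[["partial"]] / 100) *
    params$v_milk / 1e6
}

#' Maternal-diet greenhouse-gas add-on
#'
#' GHG emissions of the additional dietary intake of breastfeeding
#' mothers over a 6-month period, under a mainly plant-based diet
#' (default 69 kg CO2e per mother) or a mixed plant/animal diet (default
#' 218 kg CO2e). This is a separate module of the accounting: its result
#' is reported on its own and never folded into a cohort footprint.
#'
#' @param n_mothers number of breastfeeding mothers (>= 0), e.g. the
#'   additional mothers breastfeeding under an intervention.
#' @param pattern \code{"plant"} or \code{"mixed"}.
#' @param params a \code{\link{footprint_params}}.
#' @return kg CO2e per 6-month period (raw kg, not millions).
#' @export
#' @examples
#' maternal_diet_ghg(1000, "plant")   # 69,000 kg CO2e
maternal_diet_ghg <- function(n_mothers, pattern = c("plant", "mixed"),
                              params = footprint_params()) {
  pattern <- match.arg(pattern)
  if (!is.numeric(n_mothers) || length(n_mothers) != 1L ||
      is.na(n_mothers) || n_mothers < 0)
    stop_validation("n_mothers must be a single non-negative number")
  n_mothers * switch(pattern, plant = params$diet_plant,
                     mixed = params$diet_mixed)
}

#' Compute the full environmental footprint of a cohort
#'
#' The central entry point: composes the CMF requirement, GHG range,
#' water footprint and lost milk for one cohort into a single result.
#'
#' @inheritParams cmf_requirement
#' @return an object of class \code{footprint_result}: a list with
#'   components \code{label}, \code{births}, \code{prevalence},
#'   \code{cmf_kg} (kg/year), \code{ghg_low}, \code{ghg_high} (million kg
#'   CO2e/year), \code{water}, \code{lost_milk} (million liters/year),
#'   and the \code{params} used.
#' @export
#' @examples
#' china <- cohort_spec("China 2018", 11501936, feeding_prevalence(61.3, 32.2))
#' compute_footprint(china)
compute_footprint <- function(cohort, params = footprint_params()) {
  cmf <- cmf_requirement(cohort, params)
  ghg <- ghg_range(cmf, params)
  structure(list(label = cohort$label,
                 births = cohort$annual_births,
                 prevalence = cohort$prevalence,
                 cmf_kg = cmf,
                 ghg_low = ghg[["ghg_low"]],
                 ghg_high = ghg[["ghg_high"]],
                 water = water_use(cmf, params),
                 lost_milk = lost_milk(cohort, params),
                 params = params),
            class = "footprint_result")
}

.fp_fields <- c("cmf_kg", "ghg_low", "ghg_high", "water", "lost_milk")

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("Annual footprint of CMF feeding: %s\n", x$label))
  if (!is.null(x$prevalence))
    cat(sprintf("  Births %s; EBF/PBF %.1f%%, partial %.1f%%, non-breastfed %.1f%%\n",
                fmt_num(x$births, 0), x$prevalence[["ebf_pbf"]],
                x$prevalence[["partial"]], x$prevalence[["non_bf"]]))
  cat(sprintf("  CMF powder:       %s kg\n", fmt_num(x$cmf_kg, 0)))
  cat(sprintf("  Carbon footprint: %s - %s million kg CO2e\n",
              fmt_num(x$ghg_low), fmt_num(x$ghg_high)))
  cat(sprintf("  Water footprint:  %s million liters\n", fmt_num(x$water)))
  cat(sprintf("  Lost milk:        %s million liters\n", fmt_num(x$lost_milk)))
  invisible(x)
}

#' @export
summary.footprint_result <- function(object, ...) {
  print(object, ...)
  eq <- equivalents(object, params = object$params %||% footprint_params())
  cat(sprintf("  Equivalent to driving %s miles;\n  the water could fill %s Olympic pools\n",
              fmt_num(eq[["miles"]], 0), fmt_num(eq[["pools"]], 0)))
  invisible(object)
}

#' @export
as.data.frame.footprint_result <- function(x, ...) {
  data.frame(label = x$label, births = x$births,
             ebf_pbf = if (is.null(x$prevalence)) NA_real_ else x$prevalence[["ebf_pbf"]],
             partial = if (is.null(x$prevalence)) NA_real_ else x$prevalence[["partial"]],
             non_bf = if (is.null(x$prevalence)) NA_real_ else x$prevalence[["non_bf"]],
             lost_milk = x$lost_milk, ghg_low = x$ghg_low,
             ghg_high = x$ghg_high, water = x$water, cmf_kg = x$cmf_kg,
             stringsAsFactors = FALSE)
}

#' Everyday equivalents of a footprint
#'
#' Converts a footprint's GHG mass into vehicle-miles driven in an
#' average combustion-engine car and its water volume into Olympic
#' swimming pools.
#'
#' @param result a \code{\link{compute_footprint}} result.
#' @param basis which GHG bound to convert, \code{"high"} (default) or
#'   \code{"low"}.
#' @param params a \code{\link{footprint_params}}.
#' @return named numeric vector \code{c(miles, pools)}.
#' @export
equivalents <- function(result, basis = c("high", "low"),
                        params = footprint_params()) {
  basis <- match.arg(basis)
  stopifnot(inherits(result, "footprint_result"))
  ghg_kg <- switch(basis, high = result$ghg_high, low = result$ghg_low) * 1e6
  water_l <- result$water * 1e6
  if (ghg_kg < 0 || water_l < 0)
    stop_validation("footprint fields must be non-negative")
  c(miles = ghg_kg * params$miles_per_kg,
    pools = water_l / params$pool_volume)
}
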