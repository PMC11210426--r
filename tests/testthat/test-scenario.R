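test_that("comparison reports signed differences (counterfactual - baseline)", {
  cmp <- compare_scenarios(china_baseline(), china_counterfactual())
  expect_s3_class(cmp, "scenario_comparison")
  expect_equal(round_half_up(cmp$difference$ghg_low), -319.0)
  expect_equal(round_half_up(cmp$difference$ghg_high), -406.0)
  expect_equal(round_half_up(cmp$difference$water, 0), -137833)
  expect_equal(cmp$difference$ghg_low,
               cmp$counterfactual$ghg_low - cmp$baseline$ghg_low)
  expect_equal(unname(cmp$prevalence_delta),
               c(28.7, -24.2, -4.5), tolerance = 1e-9)
})

test_that("comparing a scenario with itself gives exactly zero", {
  cmp <- compare_scenarios(china_baseline(), china_baseline())
  for (f in names(cmp$difference)) expect_identical(cmp$difference[[f]], 0)
})

test_that("differences are antisymmetric", {
  a <- china_baseline(); b <- china_counterfactual()
  ab <- compare_scenarios(a, b)
  ba <- compare_scenarios(b, a)
  for (f in names(ab$difference))
    expect_equal(ab$difference[[f]], -ba$difference[[f]], tolerance = 1e-12)
})

test_that("mismatched birth counts warn but still compare", {
  a <- cohort_spec("a", 1000, feeding_prevalence(50, 30))
  b <- cohort_spec("b", 2000, feeding_prevalence(50, 30))
  expect_warning(compare_scenarios(a, b), "different annual births")
})

test_that("uplift applies the two-thirds partial rule", {
  indo <- feeding_prevalence(58.2, 29.9)
  up10 <- apply_uplift(indo, 10)
  expect_equal(round_half_up(unname(unclass(up10))), c(68.2, 21.2, 10.6))
  up15 <- apply_uplift(indo, 15)
  expect_equal(round_half_up(unname(unclass(up15))), c(73.2, 17.9, 8.9))
  # partial/non_bf ratio is 2 whenever any infants are not EBF/PBF
  set.seed(17)
  for (rep in 1:20) {
    base <- feeding_prevalence(stats::runif(1, 0, 80), stats::runif(1, 0, 15))
    up <- apply_uplift(base, stats::runif(1, 0, 100 - base[["ebf_pbf"]]))
    if (up[["non_bf"]] > 1e-9)
      expect_equal(up[["partial"]] / up[["non_bf"]], 2, tolerance = 1e-9)
  }
  # fixed point: a base already on the two-thirds rule is unchanged by +0
  fp <- feeding_prevalence(70, 20, 10)
  expect_equal(unclass(apply_uplift(fp, 0)), unclass(fp), tolerance = 1e-12)
  expect_error(apply_uplift(indo, 50), "> 100")
})

test_that("coverage scaling is linear and multiplicative", {
  indo15 <- cohort_spec("Indonesia +15pt", 4435250,
                        apply_uplift(feeding_prevalence(58.2, 29.9), 15))
  full <- compute_footprint(indo15)
  cov5 <- scale_coverage(full, 0.05)
  expect_equal(round_half_up(cov5$births, 0), 221763, tolerance = 1e-5)
  expect_equal(cov5$ghg_low, full$ghg_low * 0.05, tolerance = 1e-12)
  # composition: c1 then c2 equals c1*c2
  c1c2 <- scale_coverage(scale_coverage(full, 0.5), 0.4)
  c20 <- scale_coverage(full, 0.2)
  for (f in c("cmf_kg", "ghg_low", "ghg_high", "water", "lost_milk"))
    expect_equal(c1c2[[f]], c20[[f]], tolerance = 1e-12)
  expect_identical(scale_coverage(full, 1)$ghg_low, full$ghg_low)
  expect_error(scale_coverage(full, 0), "coverage")
  expect_error(scale_coverage(full, 1.2), "coverage")
})

test_that("avoided footprint is the coverage-scaled difference", {
  cmp <- compare_scenarios(china_baseline(), china_counterfactual())
  av <- avoided_footprint(cmp, 0.1)
  expect_equal(av$ghg_low, cmp$difference$ghg_low * 0.1, tolerance = 1e-12)
  expect_lt(av$ghg_low, 0)
})

test_that("extinction scenario sets 100% formula feeding and is idempotent", {
  coh <- cohort_spec("LMIC pooled", 131386401, feeding_prevalence(57.8, 9.4))
  ext <- extinction_scenario(coh)
  expect_equal(unname(unclass(ext$prevalence)), c(0, 0, 100))
  expect_equal(ext$annual_births, coh$annual_births)
  ext2 <- extinction_scenario(ext)
  expect_equal(unclass(ext2$prevalence), unclass(ext$prevalence))
  zero <- extinction_scenario(cohort_spec("z", 0, feeding_prevalence(50, 30)))
  expect_equal(compute_footprint(zero)$ghg_high, 0)
})

test_that("scenario configs load from YAML and JSON", {
  cfg <- list(
    baseline = list(label = "China 2018", births = "11,501,936",
                    prevalence = list(ebf_pbf = 61.3, partial = 32.2)),
    counterfactual = list(label = "policy",
                          prevalence = list(ebf_pbf = 90, partial = 8)),
    diet = list(pattern = "plant", mothers = 1000))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  sc <- read_scenario_config(yml)
  expect_equal(sc$baseline$cohort$annual_births, 11501936)
  expect_equal(sc$counterfactual$cohort$prevalence[["non_bf"]], 2)
  expect_equal(sc$diet$mothers, 1000)

  cfg$counterfactual <- list(label = "uplift", uplift = 10)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  sc2 <- read_scenario_config(jsn)
  expect_equal(round_half_up(sc2$counterfactual$cohort$prevalence[["ebf_pbf"]]),
               71.3)
  expect_error(read_scenario_config(tempfile()), "not found")
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(baseline = cfg$baseline), bad)
  expect_error(read_scenario_config(bad), "counterfactual")
})
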