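test_that("closed-form CMF mass agrees with per-infant enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(10:1000, 1)
    n_partial <- sample(0:n, 1)
    n_non <- sample(0:(n - n_partial), 1)
    cohort <- cohort_spec("tiny", n,
                          feeding_prevalence(100 * (n - n_partial - n_non) / n,
                                             100 * n_partial / n,
                                             100 * n_non / n))
    expect_equal(cmf_requirement(cohort),
                 cmf_by_enumeration(n_partial, n_non),
                 tolerance = 1e-9)
  }
})

test_that("CMF requirement matches hand-checked cohorts", {
  canada <- cohort_spec("Canada before", 373864, feeding_prevalence(23.1, 51.3))
  expect_equal(cmf_requirement(canada), 373864 * 8.5571, tolerance = 1e-6)
  all_bf <- cohort_spec("all bf", 5e6, feeding_prevalence(100, 0))
  expect_equal(cmf_requirement(all_bf), 0)
  ext <- cohort_spec("ext", 131386401, feeding_prevalence(0, 0, 100))
  expect_equal(cmf_requirement(ext), 2627728020)
})

test_that("GHG range and water scale linearly with fixed factor ratios", {
  p <- footprint_params()
  set.seed(3)
  for (cmf in c(1, 1e3, stats::runif(5, 1e4, 1e10))) {
    g <- ghg_range(cmf, p)
    expect_equal(g[["ghg_high"]] / g[["ghg_low"]], 14 / 11, tolerance = 1e-12)
    expect_equal(water_use(cmf, p) * 1e6 / cmf, 4752.7, tolerance = 1e-12)
  }
  expect_equal(unname(ghg_range(0)), c(0, 0))
  expect_equal(water_use(0), 0)
  expect_error(ghg_range(-1), "non-negative")
  expect_error(water_use(-1), "non-negative")
})

test_that("lost milk follows the reconstructed per-infant volumes", {
  ext <- cohort_spec("ext", 131386401, feeding_prevalence(0, 0, 100))
  expect_equal(lost_milk(ext), 131386401 * 45 / 1e6)
  all_bf <- cohort_spec("bf", 1e7, feeding_prevalence(100, 0))
  expect_equal(lost_milk(all_bf), 0)
  cf <- cohort_spec("cf", 11501936, feeding_prevalence(90, 8, 2))
  expect_equal(round_half_up(lost_milk(cf)), 15.3)
})

test_that("maternal diet add-on multiplies the per-mother constants", {
  expect_equal(maternal_diet_ghg(1000, "plant"), 69000)
  expect_equal(maternal_diet_ghg(1000, "mixed"), 218000)
  expect_equal(maternal_diet_ghg(0, "mixed"), 0)
  expect_error(maternal_diet_ghg(10, "vegan"))
  expect_error(maternal_diet_ghg(-5, "plant"), "non-negative")
})

test_that("compute_footprint composes consistently and handles zero births", {
  r <- compute_footprint(cohort_spec("Canada before", 373864,
                                     feeding_prevalence(23.1, 51.3)))
  expect_s3_class(r, "footprint_result")
  expect_equal(round_half_up(c(r$lost_milk, r$ghg_low, r$ghg_high, r$water)),
               c(5.3, 35.2, 44.8, 15204.8))
  expect_equal(r$ghg_high / r$ghg_low, 14 / 11, tolerance = 1e-12)
  expect_equal(r$water * 1e6 / r$cmf_kg, 4752.7, tolerance = 1e-12)

  z <- compute_footprint(cohort_spec("none", 0, feeding_prevalence(50, 30)))
  for (f in c("cmf_kg", "ghg_low", "ghg_high", "water", "lost_milk"))
    expect_equal(z[[f]], 0)
})

test_that("footprints are homogeneous of degree one in births", {
  set.seed(5)
  base <- compute_footprint(cohort_spec("b", 250000,
                                        feeding_prevalence(40, 35, 25)))
  for (c_ in c(0.5, 2, 10, stats::runif(3, 0.1, 100))) {
    scaled <- compute_footprint(cohort_spec("s", 250000 * c_,
                                            feeding_prevalence(40, 35, 25)))
    for (f in c("cmf_kg", "ghg_low", "ghg_high", "water", "lost_milk"))
      expect_equal(scaled[[f]], base[[f]] * c_, tolerance = 1e-12)
  }
})

test_that("shifting prevalence toward more formula never lowers a footprint", {
  fields <- c("cmf_kg", "ghg_low", "ghg_high", "water", "lost_milk")
  set.seed(9)
  for (rep in 1:20) {
    w <- stats::runif(3); w <- w / sum(w) * 100
    base <- compute_footprint(cohort_spec("b", 1e6,
                                          feeding_prevalence(w[1], w[2], w[3])))
    d <- stats::runif(1, 0, w[1])
    ebf_to_partial <- compute_footprint(
      cohort_spec("m1", 1e6, feeding_prevalence(w[1] - d, w[2] + d, w[3])))
    d2 <- stats::runif(1, 0, w[2])
    partial_to_non <- compute_footprint(
      cohort_spec("m2", 1e6, feeding_prevalence(w[1], w[2] - d2, w[3] + d2)))
    for (f in fields) {
      expect_gte(ebf_to_partial[[f]], base[[f]] - 1e-9)
      expect_gte(partial_to_non[[f]], base[[f]] - 1e-9)
    }
  }
})

test_that("full formula feeding maximizes every footprint field", {
  fields <- c("cmf_kg", "ghg_low", "ghg_high", "water", "lost_milk")
  births <- 1e6
  ext <- compute_footprint(cohort_spec("ext", births,
                                       feeding_prevalence(0, 0, 100)))
  set.seed(13)
  for (rep in 1:30) {
    w <- stats::runif(3); w <- w / sum(w) * 100
    r <- compute_footprint(cohort_spec("r", births,
                                       feeding_prevalence(w[1], w[2], w[3])))
    for (f in fields) expect_lte(r[[f]], ext[[f]] + 1e-9)
  }
})

test_that("equivalence conversions reproduce the published pairs", {
  r <- structure(list(label = "LMIC", births = NA, prevalence = NULL,
                      cmf_kg = NA, ghg_low = 5.9e3, ghg_high = 7.5e3,
                      water = 2562e3, lost_milk = NA),
                 class = "footprint_result")
  eq <- equivalents(r)
  expect_equal(eq[["miles"]], 19.3e9, tolerance = 1e-12)
  expect_equal(round(eq[["pools"]]), 819840)
  zero <- structure(list(ghg_low = 0, ghg_high = 0, water = 0),
                    class = "footprint_result")
  expect_equal(unname(equivalents(zero)), c(0, 0))
})

test_that("parameter registry validates its invariants", {
  expect_error(footprint_params(e_low = 15), "e_low")
  expect_error(footprint_params(m_partial = 25), "m_partial")
  expect_error(footprint_params(v_milk = -1), "positive")
  expect_error(apply_param_overrides(list(bogus = 1)), "unknown parameter")
  p <- apply_param_overrides(list(e_low = "12", e_high = "13"))
  expect_equal(p$e_low, 12)
  expect_equal(p$e_high, 13)
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(15204.75, 1), 15204.8)
  expect_equal(round_half_up(2.5, 0), 3)
})
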