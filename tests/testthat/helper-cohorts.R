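# Shared fixtures: small helpers used across test files.

china_baseline <- function() {
  cohort_spec("China 2018", 11501936, feeding_prevalence(61.3, 32.2))
}

china_counterfactual <- function() {
  cohort_spec("China counterfactual", 11501936, feeding_prevalence(90, 8))
}

# Independent per-infant oracle: loop over infants, adding each one's
# 6-month CMF mass. Intentionally naive; must stay free of the closed form.
cmf_by_enumeration <- function(n_partial, n_non_bf, m_partial = 6.7,
                               m_full = 20) {
  total <- 0
  for (i in seq_len(n_partial)) total <- total + m_partial
  for (i in seq_len(n_non_bf)) total <- total + m_full
  total
}

# Printed-precision comparison: round to the table's precision, compare
# with relative tolerance 1e-3.
expect_printed <- function(x, printed, digits = 1) {
  expect_equal(round_half_up(x, digits), printed, tolerance = 1e-3)
}
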