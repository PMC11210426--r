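---
title: "Methods: environmental footprint accounting for formula feeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental footprint accounting for formula feeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formulafootprint)
```

## The accounting model

The package estimates the environmental cost of commercial milk formula
(CMF) feeding for a population of infants under six months. The model is
deliberately linear: every quantity is a product of a population count,
a prevalence share and a per-infant or per-kilogram constant. That makes
it transparent, auditable and exactly reproducible — properties that
matter more than realism in a tool meant to support policy argument and
carbon-offset accounting, where every figure must be traceable to a
stated constant.

Infants are partitioned into three mutually exclusive feeding
categories: exclusively or predominantly breastfed (EBF/PBF, merged
because both imply essentially zero CMF intake), partially breastfed
(mixed feeding, assumed to draw one third of intake from CMF), and
non-breastfed (fully CMF-fed). For a cohort with annual births $B$ and
shares $p_{ebf}, p_{part}, p_{non}$ (percent, summing to 100):

$$M = B\left(\frac{p_{part}}{100}\, m_{part} + \frac{p_{non}}{100}\, m_{full}\right)
\qquad \text{kg CMF powder per year,}$$

with $m_{full} = 20$ kg per non-breastfed infant over the six-month
period (a humanitarian-protocol figure that includes stock waste) and
$m_{part} = 6.7$ kg $\approx m_{full}/3$. GHG emissions are
$M \times e$ with lifecycle emission factors $e = 11$ (lower bound) and
$14$ (upper bound) kg CO₂e per kg powder; the water footprint is
$M \times w$ with $w = 4752.7$ L/kg; lost milk is
$B\,(p_{non}/100 + \alpha\, p_{part}/100)\, v$ with $v = 45$ L per fully
formula-fed infant and $\alpha = 0.12$ for partially breastfed infants.
Results are reported in the units of published country tables: million
kg CO₂e and million liters per year.

### Key modelling conventions

**The infant population equals annual live births.** Although "infants
under six months" suggests half a birth cohort, the published country
figures are only reproducible when the full annual birth count enters
the formula with six-month per-infant masses. We therefore treat the
per-infant constants as "per infant passing through the under-6-month
window in a year", and document this prominently because it is the
single largest potential misreading of the model.

**Derived constants.** The operative water intensity is nowhere stated
as a single number in the source literature, which gives a total
(blue + green + grey) production footprint of 4,700–7,430 L/kg plus
about 7 L reconstitution and 56 L washing per kg prepared. We
back-derived $w = 12{,}488{,}803.0 \times 10^6 / (131{,}386{,}401
\times 20) = 4752.7$ L/kg from the all-formula scenario's printed water
figure divided by its CMF mass, and cross-validated it against every
other printed water cell (all match to the printed digit). It sits
inside the cited range but matches no stated combination exactly; its
provenance is recorded as derived, not published. The lost-milk
constants $v = 45$ L and $\alpha = 0.12$ were derived the same way
(extinction row: $5{,}912.4 \times 10^6 / 131{,}386{,}401 = 45.0$) and
validated against seven printed lost-milk cells. The equivalence
factors (2.5733 vehicle-miles per kg CO₂e; 3,125,000 L per Olympic
pool) are quotients of published example pairs, so rendered equivalents
match the published narrative rather than any external converter.

**Percentages stay on the 0–100 scale end to end**; they become
fractions only inside arithmetic. Internal arithmetic is full
precision; display rounds half away from zero to one decimal in
millions through a single shared routine (base R's `round()` rounds
half to even, which would print 15,204.75 as 15,204.7 rather than the
published 15,204.8).

## Tunable parameters

All constants live in one registry, `footprint_params()`, each with
units and provenance in its documentation:

| parameter | default | units | provenance |
|---|---|---|---|
| `m_full` | 20 | kg powder / non-breastfed infant / 6 mo | published |
| `m_partial` | 6.7 | kg powder / partial infant / 6 mo | published |
| `e_low`, `e_high` | 11, 14 | kg CO₂e / kg powder | published |
| `w_intensity` | 4752.7 | L / kg powder | derived (above) |
| `v_milk` | 45 | L / non-breastfed infant / 6 mo | derived |
| `alpha_partial` | 0.12 | fraction of `v_milk` per partial infant | derived |
| `diet_plant`, `diet_mixed` | 69, 218 | kg CO₂e / mother / 6 mo | published |
| `miles_per_kg` | 19.3/7.5 | miles / kg CO₂e | derived quotient |
| `pool_volume` | 3,125,000 | L / pool | derived quotient |

Overrides are validated against the registry's invariants
(`e_low <= e_high`, `m_partial <= m_full`, all positive) before any
computation, and are exposed as CLI flags so sensitivity analyses over
the literature ranges (emission factor 11–14, water 4,700–7,430) are
one-line operations.

## Scenarios

`compare_scenarios()` reports baseline, counterfactual and their signed
fieldwise differences; a negative difference is an avoided emission,
and the negated GHG difference is the intervention's additionality in
carbon-offset terms. Counterfactual prevalence can be given directly or
constructed by `apply_uplift()`, which raises EBF/PBF by a stated
number of percentage points and splits the remainder two-thirds partial
/ one-third non-breastfed — the convention used for facility-based
breastfeeding-support scenarios. Neither route is privileged.

**Coverage semantics.** `scale_coverage()` multiplies every footprint
field and the birth count by the coverage fraction: it reports the
footprint *of the covered subpopulation at scenario rates* (5% coverage
of a 149.3-unit scenario is 7.5), because that is how published
coverage rows are constructed. The different quantity "covered share of
the baseline-to-scenario difference" is deliberately a separate,
distinctly named helper, `avoided_footprint()`, to prevent the two
being conflated.

The maternal-diet module is kept separate by design: the number of
additional breastfeeding mothers under an intervention is supplied by
the user, not inferred from a prevalence category, and its GHG add-on
is reported alongside, never folded into, a cohort footprint — folding
it in would silently shrink claimed additionality.

`extinction_scenario()` replaces any prevalence with (0, 0, 100),
the hypothetical in which all breastfeeding under six months is
displaced by formula. It is idempotent and, by the model's
monotonicity, maximizes every footprint field for fixed births.

## Validation and normalization rules

Prevalence records may omit exactly one category, which is completed as
the complement of the other two (surveys typically report exclusive and
partial rates only). A derived complement in $[-0.1, 0)$ — survey
rounding — clamps to zero; anything more negative is rejected as a
data-entry error rather than silently corrected. Complete records must
sum to 100 within 0.1 percentage points. Band-level data (0–1, 2–3,
4–5 months) aggregates by the unweighted mean, which equals the
under-six-months share under a uniform age distribution; when both
band-level and aggregate prevalence are supplied they must agree within
0.5 points. Batch table reads never abort on a bad row: rows failing
validation are retained, flagged with a reason, and surfaced in a
diagnostics report, while rows with empty prevalence cells are marked
"no data" (rendered as "–" in human reports, nulls in machine output).

## The synthetic table generator

`generate_fixtures()` emulates the structure of UNICEF-style country
indicator tables: log-uniform births in $[10^4, 3 \times 10^7]$
(spanning small states to the most populous countries), prevalence
triplets from a Dirichlet distribution with concentration (5, 3, 1) —
chosen once as a realistic breastfeeding-majority profile with
occasional high-formula countries — rounded to one decimal as surveys
report, a configurable fraction of "no data" rows, and the four
published reference cohorts embedded verbatim as known-answer rows. It
is a pure function of (n, seed, config) and restores the caller's RNG
state. What it does *not* emulate: correlation between a country's
income level and its feeding profile, within-country age-band
structure, survey sampling error, or multi-year survey series. Tests
passing on these fixtures therefore demonstrate the arithmetic,
validation and round-trip machinery — not calibration against any real
survey.

## Numerical choices and degenerate inputs

Everything is closed-form; there is no optimisation, iteration or
tolerance beyond the validation bands above. Zero births yield an
all-zero result rather than an error. Ties in fixture-share rounding
are resolved by adding the rounding drift to the largest share.
Comparisons of computed against published figures in the test suite
round to the printed precision and then compare with relative tolerance
$10^{-3}$. Problem sizes are small throughout — cohorts are single
rows of arithmetic, brute-force per-infant oracles run on cohorts of at
most 1,000 infants, and property checks use 20–30 seeded draws — which
keeps the full suite to a few seconds while exercising every operation.

## Known limitations

- One published scenario row (a 15-point uplift) prints carbon and
  water cells inconsistent with its own printed prevalence (implying
  ~9.3% non-breastfed instead of the stated 8.9%), while its lost-milk
  cell is consistent; the package reproduces the model, not that row,
  and we treat it as a source inconsistency.
- One published preloaded lost-milk figure (Indonesia, 96.1) cannot be
  obtained from aggregate prevalence with the derived constants,
  suggesting the original preloaded path uses age-band-specific milk
  volumes; the band-level survey data needed to test this is not
  published, so the package models lost milk from aggregate prevalence
  only.
- The model covers infants under six months only: follow-on formula for
  older children, breast-pump and milk-bank emissions, packaging waste,
  fertility/child-spacing feedbacks, and the emissions of breastfeeding
  itself are all out of scope, as is live retrieval from survey
  databases.
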