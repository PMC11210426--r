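Package: formulafootprint
Title: Environmental Footprint of Commercial Milk Formula Feeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the commercial milk formula (CMF) requirements,
    greenhouse-gas emissions, water footprint and "lost milk" of a
    population of infants under six months of age from
    breastfeeding-prevalence data, and compares baseline against
    counterfactual feeding scenarios (policy uplifts, intervention
    coverage fractions, and a breastfeeding-extinction scenario) in the
    framework used for carbon-offset additionality accounting. Includes
    readers and writers for country indicator tables, a seeded synthetic
    fixture generator emulating UNICEF-IYCF-style survey tables, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
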