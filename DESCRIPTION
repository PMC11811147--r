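Package: multiyield
Title: Thermodynamic Black-Box Models of Overall Biomass Yield on
    Multiple Nutrient Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an expanded thermodynamic black-box model of microbial
    growth in batch culture, in which the Gibbs energy released by catabolism of
    degradable nutrients balances the dissipation and anabolic costs of biomass
    formation, extended with phenomenological mutual-effect coefficients between
    nutrient sources and with externally supplied non-degradable biomass
    precursors. Provides the closed-form produced-biomass solutions (including
    the quadratic precursor model with saturation branching), an independent
    numeric energy-balance solver, a plate-reader growth-curve processing
    pipeline (optical-density linearisation, dry-weight conversion, endpoint
    extraction, growth-rate and diauxic-phase estimation), overall-yield
    estimation by linear and segmented fits, nonlinear least-squares recovery of
    mutual-effect coefficients with a classed model object and standard methods,
    qualitative solution-space mapping, and seeded synthetic-data generators for
    endpoint tables, diauxic plates and acetate-secretion assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
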