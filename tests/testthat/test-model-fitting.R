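test_that("two-degradable coefficients are recovered exactly from noiseless data", {
  p <- demo_params_two()
  eff <- two_degradable_effects(m_cat_1 = 0.004)
  des <- endpoint_design(measured_amounts = seq(0, 240, 40),
                         base_amounts = c(0, 80, 160), noise_cv = 0, seed = 1)
  fit <- fit_mutual_effects(generate_endpoint_table(p, des, effects = eff)$endpoints,
                            model = "two_degradable")
  truth <- c(Y1 = 0.5, Y2 = 0.3, delta = 0.002, alpha1 = 0, alpha2 = 0)
  expect_equal(coef(fit), truth, tolerance = 1e-8)
  expect_lt(fit$sse, 1e-16)
})

test_that("two-degradable recovery from noisy triplicates stays within 10%", {
  p <- demo_params_two()
  eff <- two_degradable_effects(m_cat_1 = 0.004)
  des <- endpoint_design(measured_amounts = seq(0, 240, 48),
                         base_amounts = c(0, 80, 160),
                         n_reps = 3, noise_cv = 0.02, seed = 42)
  fit <- fit_mutual_effects(generate_endpoint_table(p, des, effects = eff)$endpoints,
                            model = "two_degradable")
  truth <- c(Y1 = 0.5, Y2 = 0.3, delta = 0.002)
  expect_lt(max(abs((coef(fit)[names(truth)] - truth) / truth)), 0.10)
  # anabolic coefficients are truly zero: estimates inside 2 SE of zero
  expect_true(all(abs(coef(fit)[c("alpha1", "alpha2")]) <=
                  2 * fit$se[c("alpha1", "alpha2")]))
})

test_that("additive data yield a null interaction estimate", {
  p <- demo_params_two()
  des <- endpoint_design(noise_cv = 0.02, seed = 9)
  fit <- fit_mutual_effects(generate_endpoint_table(p, des)$endpoints,
                            model = "two_degradable")
  expect_lte(abs(coef(fit)[["delta"]]), 2 * fit$se[["delta"]])
  expect_equal(classify_mutual_effect(fit)$catabolic, "none")
})

test_that("designs with one base amount are rejected as unidentifiable", {
  p <- demo_params_two()
  gen <- generate_endpoint_table(p, endpoint_design(base_amounts = 160,
                                                    noise_cv = 0, seed = 1))
  expect_error(fit_mutual_effects(gen$endpoints, "two_degradable"),
               class = "multiyield_identifiability_error")
})

test_that("precursor coefficients are recovered with correct signs", {
  p <- demo_params_prec()
  eff <- precursor_effects(m_cat = -0.8, m_bsyn = 0.05)
  truth <- prec_truth(eff)
  des <- endpoint_design(measured_amounts = prec_measured_amounts(),
                         base_amounts = c(40, 80, 160), noise_cv = 0, seed = 5)
  gen <- generate_endpoint_table(p, des, effects = eff, q_req = 0.02)
  fit <- fit_mutual_effects(gen$endpoints, "precursor", q_req = 0.02)
  expect_equal(coef(fit), truth, tolerance = 1e-6)
  expect_lt(coef(fit)[["m_cat"]], 0)
  expect_gt(coef(fit)[["beta_MN"]], 0)
  expect_lt(max(abs((coef(fit) - truth) / truth)), 0.05)
})

test_that("zero-coefficient precursor data give null effect estimates", {
  p <- demo_params_prec()
  des <- endpoint_design(measured_amounts = prec_measured_amounts(),
                         base_amounts = c(40, 80, 160), noise_cv = 0.02,
                         seed = 13)
  gen <- generate_endpoint_table(p, des, effects = precursor_effects(),
                                 q_req = 0.02)
  fit <- fit_mutual_effects(gen$endpoints, "precursor", q_req = 0.02)
  for (nm in c("m_cat", "alpha_N", "beta_MN"))
    expect_lte(abs(coef(fit)[[nm]]), 2 * fit$se[[nm]])
  cl <- classify_mutual_effect(fit)
  expect_equal(cl$catabolic, "none")
  expect_equal(cl$biosynthesis, "none")
})

test_that("effect classification applies the two-standard-error rule", {
  mk <- function(model, coefs, ses) {
    structure(list(coefficients = coefs, se = ses, model = model),
              class = "mutual_fit")
  }
  f1 <- mk("two_degradable",
           c(Y1 = 0.5, Y2 = 0.3, delta = 0.002, alpha1 = 0, alpha2 = 0),
           c(Y1 = 0.01, Y2 = 0.01, delta = 3e-4, alpha1 = 1e-4, alpha2 = 1e-4))
  expect_equal(classify_mutual_effect(f1)$catabolic, "positive")
  f2 <- mk("precursor",
           c(y_N = 0.4, m_cat = -0.8, beta_M = 0.1, alpha_N = 0, beta_MN = 0),
           c(y_N = 0.01, m_cat = 0.1, beta_M = 0.01, alpha_N = 1e-4, beta_MN = 1e-4))
  expect_equal(classify_mutual_effect(f2)$catabolic, "negative")
  f3 <- mk("two_degradable",
           c(Y1 = 0.5, Y2 = 0.3, delta = 0.001, alpha1 = 0, alpha2 = 0),
           c(Y1 = 0.01, Y2 = 0.01, delta = 0.002, alpha1 = 1e-4, alpha2 = 1e-4))
  expect_equal(classify_mutual_effect(f3)$catabolic, "none")
  # without a covariance the labels are reported but confidence is withheld
  f4 <- mk("two_degradable", coef(f1), rep(NA_real_, 5))
  names(f4$se) <- names(coef(f1))
  cl <- classify_mutual_effect(f4)
  expect_false(cl$confidence)
  expect_equal(cl$catabolic, "none")
})

test_that("regime mapping labels the qualitative solution space", {
  p <- demo_params_two()
  des <- list(measured_amounts = seq(0, 240, by = 12), base_amount = 160)
  eff_list <- list(zero = two_degradable_effects(),
                   pos = two_degradable_effects(m_cat_1 = 0.004),
                   neg = two_degradable_effects(m_cat_1 = -0.002),
                   bad = two_degradable_effects(m_an_1 = -0.05))
  rm <- map_solution_space(p, eff_list, des)
  expect_equal(rm$label, c("additive", "yield_increase", "yield_decrease",
                           "invalid"))
})

test_that("the two-degradable model is symmetric under nutrient relabelling", {
  # relabelling nutrient 1 <-> 2 with coefficients swapped leaves the
  # produced biomass (and hence any regime label) unchanged
  set.seed(55)
  for (k in 1:25) {
    g <- runif(2, 50, 400)
    p12 <- energy_params(300, c(N1 = g[1], N2 = g[2]), 100)
    p21 <- energy_params(300, c(N2 = g[2], N1 = g[1]), 100)
    mc <- runif(2, -0.001, 0.004); ma <- runif(2, 0, 5e-4)
    e12 <- two_degradable_effects(mc[1], mc[2], ma[1], ma[2])
    e21 <- two_degradable_effects(mc[2], mc[1], ma[2], ma[1])
    a <- runif(1, 0, 240); b <- runif(1, 0, 160)
    expect_equal(produced_biomass_two_degradable(p12, e12, a, b),
                 produced_biomass_two_degradable(p21, e21, b, a,
                                                 nutrient_ids = c("N2", "N1")),
                 tolerance = 1e-12)
  }
})

test_that("precursor sweeps with negative catabolic coupling map to yield loss", {
  # the saturated branch is constant in the precursor amount, so a strongly
  # negative catabolic coupling produces a weakly decreasing sweep (no
  # interior extremum); the mapper reports the yield decrease it computes
  p <- demo_params_prec()
  des <- list(measured_amounts = seq(0, 3, by = 0.1), base_amount = 80)
  rm <- map_solution_space(p, list(precursor_effects(m_cat = -0.8,
                                                     m_bsyn = 0.05)),
                           des, spec = precursor_spec(0.02))
  expect_equal(rm$label, "yield_decrease")
})

test_that("fitted yields increase with base amount in yield-increase regimes", {
  p <- demo_params_two()
  eff <- two_degradable_effects(m_cat_1 = 0.004)
  des <- endpoint_design(measured_amounts = seq(0, 240, 40),
                         base_amounts = c(0, 40, 80, 120, 160),
                         noise_cv = 0, seed = 2)
  gen <- generate_endpoint_table(p, des, effects = eff)
  yields <- vapply(split(as.data.frame(gen$endpoints),
                         gen$endpoints$base_amount_ug),
                   function(d) fit_overall_yield(d)$slope, 0)
  expect_true(all(diff(yields) > 0))
})
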