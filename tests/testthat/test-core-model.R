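test_that("single-nutrient overall yield follows the energy balance", {
  p <- demo_params_single()
  expect_equal(overall_yield_single(p), 0.5)
  pp <- demo_params_prec()
  expect_equal(overall_yield_single(pp, m_utl = 0), 200 / 450)
  expect_equal(overall_yield_single(pp, m_utl = 1), 0.5)
  # external precursor supply alleviates the biosynthesis cost
  expect_gt(overall_yield_single(pp, m_utl = 1),
            overall_yield_single(pp, m_utl = 0))
  expect_error(overall_yield_single(p, "unknown"), "unknown nutrient")
  expect_error(overall_yield_single(pp, m_utl = 1.5),
               class = "multiyield_validity_error")
})

test_that("energy parameter invariants are enforced", {
  expect_error(energy_params(g_X = 0, g_cat = c(a = 1), g_an = 1),
               class = "multiyield_validity_error")
  expect_error(energy_params(g_X = 1, g_cat = c(a = 0), g_an = 1),
               class = "multiyield_validity_error")
  expect_error(energy_params(g_X = 1, g_cat = c(a = 1), g_an = 1,
                             g_an_excl = 2, g_bsyn = 0),
               class = "multiyield_validity_error")
  expect_error(precursor_effects(m_cat = -1),
               class = "multiyield_validity_error")
})

test_that("produced biomass is linear in amount and yield", {
  expect_equal(produced_biomass_linear(0.5, 10), 5)
  expect_equal(produced_biomass_linear(0.5, 0), 0)
  expect_equal(produced_biomass_linear(overall_yield_single(demo_params_single()), 4), 2)
  expect_error(produced_biomass_linear(-0.1, 1),
               class = "multiyield_validity_error")
})

test_that("additive model sums nutrient contributions symmetrically", {
  p <- energy_params(g_X = 300, g_cat = c(a = 200, b = 120), g_an = 100)
  expect_equal(produced_biomass_additive(p, c(a = 10, b = 5)), 0.5 * 10 + 0.3 * 5)
  expect_equal(produced_biomass_additive(p, c(a = 10)),
               produced_biomass_linear(0.5, 10))
  expect_equal(produced_biomass_additive(p, c(b = 5, a = 10)),
               produced_biomass_additive(p, c(a = 10, b = 5)))
  expect_error(produced_biomass_additive(p, numeric(0)), "empty")
})

test_that("two-degradable model matches hand-computed cases and reduces to additive", {
  p <- energy_params(g_X = 300, g_cat = c(N1 = 100, N2 = 100), g_an = 100)
  expect_equal(produced_biomass_two_degradable(p, two_degradable_effects(), 1, 1), 0.5)
  expect_equal(produced_biomass_two_degradable(
    p, two_degradable_effects(m_cat_1 = 0.1, m_cat_2 = 0.1), 1, 1), 0.55)
  expect_equal(produced_biomass_two_degradable(
    p, two_degradable_effects(m_an_1 = 1), 1, 0), 100 / 500)
  expect_error(produced_biomass_two_degradable(
    p, two_degradable_effects(m_an_1 = -2), 1, 1),
    class = "multiyield_validity_error")
})

test_that("zero mutual-effect coefficients reproduce the additive sum exactly", {
  set.seed(101)
  for (k in 1:100) {
    p <- energy_params(g_X = runif(1, 100, 500),
                       g_cat = c(a = runif(1, 50, 400), b = runif(1, 50, 400)),
                       g_an = runif(1, 20, 300))
    N1 <- runif(1, 0, 250); N2 <- runif(1, 0, 250)
    expect_equal(produced_biomass_two_degradable(p, two_degradable_effects(), N1, N2),
                 produced_biomass_additive(p, c(a = N1, b = N2)),
                 tolerance = 1e-12)
  }
})

test_that("produced biomass increases with the catabolic coupling", {
  p <- demo_params_two()
  ms <- seq(-0.002, 0.006, by = 0.001)
  dB <- vapply(ms, function(m) produced_biomass_two_degradable(
    p, two_degradable_effects(m_cat_1 = m), 120, 160), 0)
  expect_true(all(diff(dB) > 0))
  # precursor variant at fixed M > 0
  pp <- demo_params_prec(); sp <- precursor_spec(0.02)
  dBp <- vapply(seq(0, 1, by = 0.2), function(m) produced_biomass_precursor(
    pp, precursor_effects(m_cat = m), sp, N = 1, M = 0.004)$delta_B, 0)
  expect_true(all(diff(dBp) > 0))
})

test_that("the yield slope responds linearly to the base amount", {
  # with m_an = 0 the derivative dB/dN1 is (g_cat1 + dm_CAT * N2)/(g_X + g_an)
  p <- demo_params_two()
  eff <- two_degradable_effects(m_cat_1 = 0.003, m_cat_2 = 0.001)
  dm <- 200 * 0.003 + 120 * 0.001
  h <- 1e-5
  for (N2 in c(0, 50, 160)) {
    num <- (produced_biomass_two_degradable(p, eff, 100 + h, N2) -
            produced_biomass_two_degradable(p, eff, 100 - h, N2)) / (2 * h)
    expect_equal(num, (200 + dm * N2) / 400, tolerance = 1e-6)
  }
})

test_that("precursor utilisation fraction is a capped ratio", {
  sp <- precursor_spec(1)
  expect_equal(m_utl_value(2, sp, 5), 0.4)
  expect_equal(m_utl_value(10, sp, 5), 1)
  expect_equal(m_utl_value(0, sp, 5), 0)
  expect_equal(m_utl_value(1, sp, 0), 1)  # vanishing need is fully covered
  expect_error(m_utl_value(-1, sp, 5), class = "multiyield_validity_error")
})

test_that("precursor quadratic reproduces its degenerate closed forms", {
  p <- demo_params_prec(); sp <- precursor_spec(0.02)
  eff0 <- precursor_effects()
  s0 <- produced_biomass_precursor(p, eff0, sp, N = 1, M = 0)
  expect_equal(s0$delta_B, 200 / 450, tolerance = 1e-12)
  expect_equal(s0$branch, "unsaturated")
  expect_equal(s0$m_utl, 0)
  expect_equal(s0$delta_B, overall_yield_single(p, m_utl = 0) * 1,
               tolerance = 1e-12)
  # M' = 0.2: with m_cat = m_an_M = 0 the constant term vanishes and
  # dB = (N g_cat + g_bsyn M')/G_A
  s1 <- produced_biomass_precursor(p, eff0, sp, N = 1, M = 0.004)
  expect_equal(s1$delta_B, 210 / 450, tolerance = 1e-12)
  expect_equal(s1$m_utl, 0.2 / (210 / 450), tolerance = 1e-9)
  # precursor in excess: saturated branch, biosynthesis cost alleviated
  s2 <- produced_biomass_precursor(p, eff0, sp, N = 1, M = 0.5)
  expect_equal(s2$branch, "saturated")
  expect_equal(s2$m_utl, 1)
  expect_equal(s2$delta_B, 200 / 400, tolerance = 1e-12)
})

test_that("precursor benefit is monotone and saturates without catabolic coupling", {
  p <- demo_params_prec(); sp <- precursor_spec(0.02)
  eff <- precursor_effects(m_bsyn = 0.05)
  Ms <- seq(0, 0.03, length.out = 40)
  sols <- lapply(Ms, function(M) produced_biomass_precursor(p, eff, sp, 1, M))
  dB <- vapply(sols, `[[`, 0, "delta_B")
  branch <- vapply(sols, `[[`, "", "branch")
  expect_true(all(diff(dB) >= -1e-12))
  sat <- which(branch == "saturated")
  expect_true(length(sat) > 2)
  expect_lt(diff(range(dB[sat])), 1e-12)
})

test_that("strong negative catabolic coupling gives a weakly monotone sweep with a saturated plateau", {
  # frozen from the numeric energy-balance oracle: the sweep decreases on the
  # unsaturated branch, then drops to the constant saturated level; the
  # closed form tracks the oracle across the branch change
  p <- demo_params_prec(); sp <- precursor_spec(0.02)
  eff <- precursor_effects(m_cat = -0.8)
  Ms <- seq(0, 0.01, length.out = 21)
  dB <- vapply(Ms, function(M)
    produced_biomass_precursor(p, eff, sp, 1, M)$delta_B, 0)
  num <- vapply(Ms, function(M)
    solve_energy_balance_numeric(p, eff, sp, 1, M), 0)
  expect_lt(max(abs(dB - num) / pmax(num, 1e-12)), 1e-8)
  expect_true(all(diff(dB) <= 1e-12))
  expect_equal(dB[1], 200 / 450, tolerance = 1e-12)
  expect_equal(dB[21], 200 * 0.2 / 400, tolerance = 1e-10)  # saturated level
})

test_that("closed-form quadratic agrees with the numeric balance on random draws", {
  set.seed(202)
  n_ok <- 0
  while (n_ok < 50) {
    cs <- random_precursor_case()
    sol <- tryCatch(produced_biomass_precursor(cs$params, cs$effects, cs$spec,
                                               cs$N, cs$M),
                    multiyield_validity_error = function(e) NULL)
    if (is.null(sol)) next
    num <- solve_energy_balance_numeric(cs$params, cs$effects, cs$spec,
                                        cs$N, cs$M)
    expect_equal(sol$delta_B, num, tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("model validity violations raise structured errors", {
  p <- demo_params_prec(); sp <- precursor_spec(0.02)
  expect_error(produced_biomass_precursor(p, precursor_effects(m_an_N = -5),
                                          sp, N = 1, M = 0),
               class = "multiyield_validity_error")
  expect_error(produced_biomass_precursor(p, precursor_effects(), sp,
                                          N = -1, M = 0),
               class = "multiyield_validity_error")
})
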