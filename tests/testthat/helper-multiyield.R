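# shared fixtures: small parameter sets and curve builders used across tests

demo_params_single <- function() {
  energy_params(g_X = 300, g_cat = c(glc = 200), g_an = 100)
}

demo_params_two <- function() {
  energy_params(g_X = 300, g_cat = c(N1 = 200, N2 = 120), g_an = 100)
}

# precursor split: g_an = g_an_excl + biosynthesis headroom, g_bsyn separate
demo_params_prec <- function() {
  energy_params(g_X = 300, g_cat = c(glc = 200), g_an = 150,
                g_an_excl = 100, g_bsyn = 50)
}

# reduced-parameter truth for demo_params_prec() + given effects
prec_truth <- function(effects, params = demo_params_prec()) {
  red <- multiyield:::.reduce_precursor(params, effects)
  c(y_N = unname(params$g_cat[1]) / red$G_A0, m_cat = red$m_cat,
    beta_M = red$beta_M, alpha_N = red$alpha_N, beta_MN = red$beta_MN)
}

# precursor titration design: dense below saturation, sparse above
prec_measured_amounts <- function() c(seq(0, 0.5, by = 0.05), 0.7, 1, 1.5, 2, 3)

# piecewise two-exponential diauxic biomass curve sampled every 10 min
make_diauxic_traj <- function(mu1 = 0.9, mu2 = 0.3, t_phase1_end = 4,
                              t_phase2_start = 7, t_phase2_end = 11,
                              b0 = 2, horizon = 16) {
  t <- seq(0, horizon, by = 1 / 6)
  b1 <- b0 * exp(mu1 * t_phase1_end)
  bend <- b1 * exp(mu2 * (t_phase2_end - t_phase2_start))
  b <- ifelse(t <= t_phase1_end, b0 * exp(mu1 * t),
       ifelse(t <= t_phase2_start, b1,
       ifelse(t <= t_phase2_end, b1 * exp(mu2 * (t - t_phase2_start)), bend)))
  data.frame(time_h = t, biomass_ug = b)
}

# random valid precursor parameter draw (list of params/effects/spec/N/M);
# rejection-free ranges keep G_A and f_cat positive
random_precursor_case <- function() {
  params <- energy_params(g_X = runif(1, 100, 500),
                          g_cat = c(glc = runif(1, 100, 400)),
                          g_an = 400,
                          g_an_excl = runif(1, 50, 200),
                          g_bsyn = runif(1, 10, 100))
  effects <- precursor_effects(m_cat = runif(1, -0.9, 1),
                               m_an_N = runif(1, -0.05, 0.2),
                               m_an_M = runif(1, -0.5, 0.5),
                               m_bsyn = runif(1, -0.05, 0.2))
  list(params = params, effects = effects, spec = precursor_spec(0.02),
       N = runif(1, 0.5, 2), M = runif(1, 0, 0.02))
}
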