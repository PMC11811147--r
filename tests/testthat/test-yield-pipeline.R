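test_that("replicate averaging gives means, standard errors and stable order", {
  pw <- data.frame(well = c("a", "b", "c"),
                   measured_amount_ug = 10, base_amount_ug = 0,
                   delta_B_ug = c(10, 12, 14))
  tab <- average_replicates(pw)
  expect_equal(tab$delta_B_mean_ug, 12)
  expect_equal(tab$delta_B_se_ug, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(tab$n_reps, 3L)
  # single replicate: SE reported as 0 with n_reps flag
  one <- average_replicates(data.frame(measured_amount_ug = 5,
                                       base_amount_ug = 0, delta_B_ug = 7))
  expect_equal(one$delta_B_se_ug, 0)
  expect_equal(one$n_reps, 1L)
  # permuting input rows leaves the table identical
  pw2 <- rbind(pw, data.frame(well = c("d", "e"), measured_amount_ug = 5,
                              base_amount_ug = 0, delta_B_ug = c(3, 4)))
  expect_identical(average_replicates(pw2),
                   average_replicates(pw2[sample(nrow(pw2)), ]))
  expect_error(average_replicates(rbind(pw, pw)), "duplicate")
})

test_that("linear-region detection matches brute-force window enumeration", {
  mk <- function(y) {
    structure(data.frame(measured_amount_ug = seq_along(y) * 10,
                         base_amount_ug = 0, delta_B_mean_ug = y,
                         delta_B_se_ug = 0, n_reps = 3L),
              class = c("endpoint_table", "data.frame"))
  }
  # exactly collinear points: the whole table qualifies
  expect_equal(detect_linear_region(mk(0.5 * (1:8))), c(1L, 8L))
  # 6 collinear points then 4 on a very different slope: independent
  # enumeration over all contiguous windows (via lm) picks the same run
  y <- c(0.5 * (1:6), 3 + 5 * (1:4))
  tab <- mk(y)
  brute <- NULL
  for (len in nrow(tab):4) for (i in 1:(nrow(tab) - len + 1)) {
    j <- i + len - 1
    r2 <- suppressWarnings(
      summary(lm(delta_B_mean_ug ~ measured_amount_ug, tab[i:j, ]))$r.squared)
    if (r2 >= 0.9 && (is.null(brute) || len > brute$len ||
                      (len == brute$len && r2 > brute$r2 + 1e-12)))
      brute <- list(i = i, j = j, len = len, r2 = r2)
  }
  got <- detect_linear_region(tab)
  expect_equal(got, c(brute$i, brute$j))
  # alternating zigzag has no linear window at all
  expect_error(detect_linear_region(mk(rep(c(0, 1), 5))),
               class = "multiyield_no_linear_region")
})

test_that("overall-yield fits recover slope, intercept and the R2 gate", {
  tab <- data.frame(measured_amount_ug = seq(0, 70, by = 10),
                    base_amount_ug = 0,
                    delta_B_mean_ug = 0.5 * seq(0, 70, by = 10) + 10)
  fit <- fit_overall_yield(tab)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  # noiseless model data: slope equals the programmed yield essentially exactly
  p <- demo_params_two()
  gen <- generate_endpoint_table(p, endpoint_design(base_amounts = c(0, 80),
                                                    noise_cv = 0, seed = 1))
  t0 <- gen$endpoints[gen$endpoints$base_amount_ug == 0, ]
  f0 <- fit_overall_yield(t0)
  expect_equal(f0$slope, overall_yield_single(p, "N1"), tolerance = 1e-12)
  expect_gt(f0$r2, 0.9)
})

test_that("segmented fits find the breakpoint and arbitrate against constants", {
  x <- seq(20, 240, by = 20)
  y <- ifelse(x <= 100, 0.2 * x, 0.2 * 100 + 0.6 * (x - 100))
  tab <- data.frame(measured_amount_ug = x, base_amount_ug = 0,
                    delta_B_mean_ug = y)
  seg <- fit_segmented_two_phase(tab)
  expect_equal(seg$breakpoint_ug, 100)
  expect_equal(seg$slope1, 0.2, tolerance = 1e-10)
  expect_equal(seg$slope2, 0.6, tolerance = 1e-10)
  expect_false(any(seg$constant_phase_flags))
  expect_false(seg$effectively_linear)
  # single-slope data: the two segments agree, flagged effectively linear
  lin <- tab; lin$delta_B_mean_ug <- 0.4 * x + 2
  expect_true(fit_segmented_two_phase(lin)$effectively_linear)
  # a flat phase is reported as consistent with a constant
  flat2 <- tab; flat2$delta_B_mean_ug <- ifelse(x <= 100, 0.3 * x, 30)
  segf <- fit_segmented_two_phase(flat2)
  expect_true(segf$constant_phase_flags[2])
  expect_false(segf$constant_phase_flags[1])
})

test_that("noisy two-phase data locate the breakpoint within one grid step", {
  set.seed(31)
  x <- seq(20, 240, by = 20)
  y <- ifelse(x <= 120, 0.2 * x, 0.2 * 120 + 0.6 * (x - 120))
  y <- y * (1 + rnorm(length(y), 0, 0.02))
  seg <- fit_segmented_two_phase(data.frame(measured_amount_ug = x,
                                            base_amount_ug = 0,
                                            delta_B_mean_ug = y))
  expect_lte(abs(seg$breakpoint_ug - 120), 20)
})

test_that("segmented SSE never exceeds the single-line SSE", {
  set.seed(77)
  for (k in 1:20) {
    x <- seq(10, 200, length.out = 10)
    y <- runif(1, 0.1, 0.6) * x + rnorm(10, 0, 5)
    tab <- data.frame(measured_amount_ug = x, base_amount_ug = 0,
                      delta_B_mean_ug = y)
    single_sse <- sum(residuals(lm(delta_B_mean_ug ~ measured_amount_ug, tab))^2)
    expect_lte(fit_segmented_two_phase(tab)$sse, single_sse + 1e-9)
  }
})

test_that("yield-vs-base profiles report the trend through per-base yields", {
  prof <- yield_vs_base_analysis(data.frame(base_amount_ug = c(0, 100, 200),
                                            yield = c(0.2, 0.3, 0.4)))
  expect_equal(prof$trend$slope, 0.001, tolerance = 1e-12)
  flatp <- yield_vs_base_analysis(data.frame(base_amount_ug = c(0, 100, 200),
                                             yield = rep(0.3, 3)))
  expect_equal(flatp$trend$slope, 0, tolerance = 1e-12)
  expect_error(yield_vs_base_analysis(data.frame(base_amount_ug = c(1, 1),
                                                 yield = c(1, 2))), "unique")
})

test_that("acetate secretion rate is the concentration-vs-OD slope times mu", {
  pts <- data.frame(od600 = seq(0.1, 0.5, by = 0.1),
                    acetate_mM = 2 * seq(0.1, 0.5, by = 0.1))
  r <- acetate_secretion_rate(pts, mu = 0.6)
  expect_equal(r$rate_mM_per_od_h, 1.2, tolerance = 1e-12)
  # specific-rate conversion through the dry-weight factor
  rc <- acetate_secretion_rate(pts, mu = 0.6, cal = calibration_model())
  expect_equal(rc$rate_mmol_per_gdcw_h, 1.2 / 0.396, tolerance = 1e-12)
  flat <- pts; flat$acetate_mM <- 1
  expect_equal(acetate_secretion_rate(flat, 0.6)$rate_mM_per_od_h, 0)
  expect_error(acetate_secretion_rate(pts[1:2, ], 0.6))
  expect_error(acetate_secretion_rate(pts, -1), "positive")
})
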