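#' Design of a synthetic endpoint experiment
#'
#' Describes the titration design the synthetic generators realise: the grid
#' of measured-nutrient amounts, the base-nutrient amounts held fixed within
#' each series, the replicate count per condition and the multiplicative
#' measurement noise. The defaults mirror a plate-scale batch experiment:
#' triplicates, measured amounts up to 240 ug per well, base amounts up to
#' 160 ug, and a 2 percent coefficient of variation.
#'
#' @param measured_amounts Numeric vector of measured-nutrient amounts, ug.
#' @param base_amounts Numeric vector of base-nutrient amounts, ug.
#' @param n_reps Replicates per condition (default 3).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   noise on produced biomass (default 0.02).
#' @param seed Integer seed making the generated data reproducible.
#' @return Object of class `"endpoint_design"`.
#' @export
endpoint_design <- function(measured_amounts = seq(0, 240, by = 40),
                            base_amounts = c(0, 40, 80, 160),
                            n_reps = 3L, noise_cv = 0.02, seed = 1L) {
  stopifnot(is.numeric(measured_amounts), length(measured_amounts) >= 2L,
            is.numeric(base_amounts), length(base_amounts) >= 1L,
            n_reps >= 1L, noise_cv >= 0, is.numeric(seed))
  if (any(measured_amounts < 0) || any(base_amounts < 0))
    stop_validity("amounts must be >= 0")
  structure(list(measured_amounts = sort(unique(measured_amounts)),
                 base_amounts = sort(unique(base_amounts)),
                 n_reps = as.integer(n_reps), noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "endpoint_design")
}

#' Kinetic parameters of the synthetic diauxic growth curves
#'
#' Phenomenological two-exponential kinetics used to turn a programmed
#' endpoint produced biomass into a plate-reader growth curve: exponential
#' growth at `mu1` on the preferred substrate until a fraction `phase_split`
#' of the target gain is reached, a flat inter-phase lag of `lag2_h`, then
#' exponential growth at `mu2` on the secondary substrate up to the target,
#' followed by stationary phase. The trajectory, not being the object of the
#' endpoint model, is deliberately not a mechanistic substrate-uptake model.
#'
#' @param mu1,mu2 Growth rates of the two phases, per hour, > 0.
#' @param lag2_h Lag before the second phase, hours, >= 0.
#' @param phase_split Fraction of the total gain accrued in phase 1, in
#'   (0, 1\]; 1 gives single-phase curves.
#' @param b0_ug Inoculum biomass per well, ug, > 0.
#' @param sample_interval_min Sampling interval, minutes (default 10).
#' @param horizon_h Total duration of the simulated run, hours; must cover
#'   stationary phase plus 5 h for every well.
#' @return Object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(mu1 = 0.9, mu2 = 0.35, lag2_h = 3.5,
                           phase_split = 0.6, b0_ug = 2,
                           sample_interval_min = 10, horizon_h = 24) {
  stopifnot(mu1 > 0, mu2 > 0, lag2_h >= 0, phase_split > 0, phase_split <= 1,
            b0_ug > 0, sample_interval_min > 0, horizon_h > 0)
  structure(list(mu1 = mu1, mu2 = mu2, lag2_h = lag2_h,
                 phase_split = phase_split, b0_ug = b0_ug,
                 sample_interval_min = sample_interval_min,
                 horizon_h = horizon_h),
            class = "kinetic_params")
}

# run code under a seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# model delta_B on the full design grid
.model_delta_B <- function(params, effects, q_req, measured, base) {
  if (is.null(effects)) {
    ids <- names(params$g_cat)[1:2]
    vapply(seq_along(measured), function(i)
      produced_biomass_additive(params, stats::setNames(
        c(measured[i], base[i]), ids)), 0)
  } else if (inherits(effects, "two_degradable_effects")) {
    produced_biomass_two_degradable(params, effects, N1 = measured, N2 = base)
  } else if (inherits(effects, "precursor_effects")) {
    sp <- precursor_spec(q_req)
    vapply(seq_along(measured), function(i)
      produced_biomass_precursor(params, effects, sp,
                                 N = base[i], M = measured[i])$delta_B, 0)
  } else stop("unsupported effects object")
}

#' Generate a synthetic endpoint table from the expanded model
#'
#' Realises the chosen model variant (additive when `effects` is `NULL`,
#' two-degradable, or degradable-plus-precursor) as replicated endpoint
#' data: for every condition of the design the model produced biomass is
#' multiplied by independent noise factors `1 + eps`,
#' `eps ~ Normal(0, noise_cv)` truncated at -90 percent to preserve
#' positivity. Deterministic under the design's seed.
#'
#' For the precursor variant the measured amounts are precursor amounts `M`
#' and the base amounts the degradable nutrient `N`.
#'
#' @param params An [energy_params()] object.
#' @param design An [endpoint_design()].
#' @param effects `NULL`, a [two_degradable_effects()] or a
#'   [precursor_effects()] object.
#' @param q_req Precursor requirement ratio (ug/ug), used by the precursor
#'   variant.
#' @return List with `endpoints` (the [average_replicates()] table),
#'   `replicates` (one row per well: `well`, `measured_amount_ug`,
#'   `base_amount_ug`, `replicate`, `delta_B_ug`) and `truth` (the noiseless
#'   model values per condition).
#' @export
generate_endpoint_table <- function(params, design, effects = NULL,
                                    q_req = 0.02) {
  stopifnot(inherits(params, "energy_params"), inherits(design, "endpoint_design"))
  grid <- expand.grid(measured_amount_ug = design$measured_amounts,
                      base_amount_ug = design$base_amounts,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$base_amount_ug, grid$measured_amount_ug), ]
  truth <- .model_delta_B(params, effects, q_req,
                          grid$measured_amount_ug, grid$base_amount_ug)
  n_cond <- nrow(grid)
  reps <- with_seed(design$seed, {
    eps <- stats::rnorm(n_cond * design$n_reps, 0, design$noise_cv)
    pmax(1 + eps, 0.1)
  })
  rep_tab <- data.frame(
    well = sprintf("W%03d", seq_len(n_cond * design$n_reps)),
    measured_amount_ug = rep(grid$measured_amount_ug, each = design$n_reps),
    base_amount_ug = rep(grid$base_amount_ug, each = design$n_reps),
    replicate = rep(seq_len(design$n_reps), times = n_cond),
    delta_B_ug = rep(truth, each = design$n_reps) * reps)
  list(endpoints = average_replicates(rep_tab),
       replicates = rep_tab,
       truth = cbind(grid, delta_B_true_ug = truth))
}

# piecewise two-exponential biomass at time t (vectorised over t)
.diauxic_biomass <- function(t, b0, dB, kin) {
  if (dB <= 0) return(rep(b0, length(t)))
  b_end <- b0 + dB
  b1 <- b0 + kin$phase_split * dB
  t1 <- log(b1 / b0) / kin$mu1
  t2 <- t1 + if (kin$phase_split < 1) kin$lag2_h else 0
  t3 <- t2 + if (kin$phase_split < 1) log(b_end / b1) / kin$mu2 else 0
  b <- numeric(length(t))
  b[t <= t1] <- b0 * exp(kin$mu1 * t[t <= t1])
  b[t > t1 & t <= t2] <- b1
  i3 <- t > t2 & t <= t3
  b[i3] <- b1 * exp(kin$mu2 * (t[i3] - t2))
  b[t > t3] <- b_end
  b
}

.diauxic_t3 <- function(b0, dB, kin) {
  if (dB <= 0) return(0)
  b1 <- b0 + kin$phase_split * dB
  t1 <- log(b1 / b0) / kin$mu1
  if (kin$phase_split >= 1) return(t1)
  t1 + kin$lag2_h + log((b0 + dB) / b1) / kin$mu2
}

#' Generate a synthetic diauxic plate-reader run
#'
#' Builds a full plate of OD600 time series whose endpoint produced biomass
#' obeys the expanded black-box model: per-well biomass targets are drawn by
#' [generate_endpoint_table()], each well follows the two-exponential
#' diauxic construction of [kinetic_params()], biomass is converted back to
#' raw OD through the inverse calibration, and readings are sampled at the
#' plate reader's interval with optional multiplicative observation noise.
#'
#' @inheritParams generate_endpoint_table
#' @param kin A [kinetic_params()] object.
#' @param cal A [calibration_model()].
#' @param od_noise_cv Coefficient of variation of multiplicative noise on
#'   the OD readings (default 0, noiseless trajectories).
#' @return List with `timeseries` (long data frame `well`, `time_h`,
#'   `od600`), `layout` (one row per well: condition columns and
#'   `replicate`), `endpoints` and `truth` as in
#'   [generate_endpoint_table()].
#' @export
generate_diauxic_plate <- function(params, design, kin = kinetic_params(),
                                   cal = calibration_model(), effects = NULL,
                                   q_req = 0.02, od_noise_cv = 0) {
  stopifnot(inherits(kin, "kinetic_params"), inherits(cal, "calibration_model"))
  gen <- generate_endpoint_table(params, design, effects, q_req)
  reps <- gen$replicates
  t3_max <- max(vapply(reps$delta_B_ug, function(d)
    .diauxic_t3(kin$b0_ug, d, kin), 0))
  if (kin$horizon_h < t3_max + 5)
    stop(sprintf(paste0("horizon_h = %.3g h too short: stationary phase is ",
                        "reached at %.3g h and 5 h of stationary data are ",
                        "required"), kin$horizon_h, t3_max))
  times <- seq(0, kin$horizon_h, by = kin$sample_interval_min / 60)
  od_scale <- cal$dw_per_od_l * cal$well_volume_l * 1e6
  noise <- if (od_noise_cv > 0)
    with_seed(design$seed + 1L,
              matrix(pmax(1 + stats::rnorm(nrow(reps) * length(times), 0,
                                           od_noise_cv), 0.1),
                     nrow = nrow(reps)))
  else NULL
  ts_list <- lapply(seq_len(nrow(reps)), function(i) {
    b <- .diauxic_biomass(times, kin$b0_ug, reps$delta_B_ug[i], kin)
    if (!is.null(noise)) b <- b * noise[i, ]
    data.frame(well = reps$well[i], time_h = times,
               od600 = delinearize_od(cal, b / od_scale))
  })
  layout <- data.frame(well = reps$well,
                       measured_nutrient = "measured",
                       measured_amount_ug = reps$measured_amount_ug,
                       base_nutrient = "base",
                       base_amount_ug = reps$base_amount_ug,
                       replicate = reps$replicate)
  list(timeseries = do.call(rbind, ts_list), layout = layout,
       endpoints = gen$endpoints, truth = gen$truth)
}

#' Generate a synthetic acetate-secretion dataset
#'
#' Emulates the supernatant assay behind the secretion-rate estimate: during
#' exponential growth at rate `mu`, a culture secreting acetate at
#' `true_rate` (mM per OD unit per hour) accumulates acetate linearly in OD
#' with slope `true_rate / mu`, so
#' `acetate(OD) = (true_rate / mu) * (OD - OD_0)` up to multiplicative
#' noise. [acetate_secretion_rate()] recovers `true_rate` in expectation.
#'
#' @param true_rate Programmed secretion rate, mM per OD per hour, >= 0.
#' @param mu Growth rate, per hour, > 0.
#' @param od_grid OD600 sampling points (first entry is the starting OD).
#' @param noise_cv Coefficient of variation of multiplicative noise on the
#'   acetate concentrations.
#' @param seed Integer seed.
#' @return Data frame with columns `od600` and `acetate_mM`.
#' @export
generate_acetate_dataset <- function(true_rate = 1.5, mu = 0.6,
                                     od_grid = seq(0.05, 0.5, length.out = 10),
                                     noise_cv = 0.03, seed = 1L) {
  stopifnot(is.numeric(true_rate), true_rate >= 0, mu > 0,
            is.numeric(od_grid), length(od_grid) >= 3L, noise_cv >= 0)
  ac <- (true_rate / mu) * (od_grid - od_grid[1])
  fac <- with_seed(seed,
                   pmax(1 + stats::rnorm(length(ac), 0, noise_cv), 0.1))
  data.frame(od600 = od_grid, acetate_mM = ac * fac)
}
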