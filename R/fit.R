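#' Fit mutual-effect coefficients of the expanded black-box model
#'
#' The central fitting function of the package: estimates the identifiable
#' reduced parameters of the expanded black-box growth model from an
#' endpoint table of produced biomass over a design of measured and base
#' nutrient amounts, by nonlinear least squares (Levenberg-Marquardt, with a
#' seeded multistart around least-squares-initialised values).
#'
#' Two model variants are supported:
#'
#' * `"two_degradable"` fits the reduced form
#'   \deqn{\Delta B = \frac{Y_1 N_1 + Y_2 N_2 + \delta N_1 N_2}
#'     {1 + \alpha_1 N_1 + \alpha_2 N_2}}
#'   where \eqn{N_1} is the measured and \eqn{N_2} the base amount,
#'   \eqn{Y_i = g_{cat,i} / (g_X + g_{an})} are the single-nutrient yields,
#'   \eqn{\delta = \Delta m_{CAT} / (g_X + g_{an})} the reduced catabolic
#'   interaction and \eqn{\alpha_i = g_{an} m_{an,i} / (g_X + g_{an})} the
#'   reduced anabolic coefficients. Only these combinations are identifiable
#'   from produced-biomass data: the two catabolic coefficients enter solely
#'   through \eqn{\Delta m_{CAT}}, and raw energy magnitudes are never
#'   estimated.
#'
#' * `"precursor"` fits the reduced quadratic precursor model with
#'   parameters `y_N` (base yield \eqn{g_{cat}/G_{A0}}), `m_cat`
#'   (dimensionless catabolic coupling, unchanged by reduction), `beta_M`
#'   (the precursor gain \eqn{(g_{bsyn} - g^{excl}_{an} m^M_{an})/G_{A0}}),
#'   `alpha_N` (the reduced anabolic-plus-biosynthesis N coefficient) and
#'   `beta_MN` (the reduced biosynthesis interaction
#'   \eqn{g_{bsyn} m_{bsyn}/G_{A0}}), where
#'   \eqn{G_{A0} = g_X + g^{excl}_{an} + g_{bsyn}}. The measured amount is
#'   the precursor `M`, the base amount the degradable nutrient `N`, and the
#'   requirement ratio `q_req` must be known.
#'
#' Designs with a single base amount are rejected: without variation in the
#' base amount the interaction terms are confounded with the single-nutrient
#' yields and intercept.
#'
#' @param endpoints An [average_replicates()] endpoint table (or any data
#'   frame with `measured_amount_ug`, `base_amount_ug` and either
#'   `delta_B_mean_ug` or `delta_B_ug`).
#' @param model `"two_degradable"` or `"precursor"`.
#' @param q_req Precursor requirement ratio (ug precursor per ug biomass),
#'   used by the precursor model only.
#' @param n_starts Number of multistart optimisations (default 5); starts
#'   beyond the first perturb the initial values log-uniformly within
#'   +/- 50 percent.
#' @param seed Integer seed for the multistart perturbations.
#' @param start Optional named numeric vector of starting values overriding
#'   the least-squares initialisation.
#' @return Object of class `"mutual_fit"` with components `coefficients`,
#'   `se`, `vcov`, `fitted.values`, `residuals`, `sse`, `sigma`, `df.residual`,
#'   `model`, `q_req`, `data`, `n_starts_converged`, `call`. Standard methods
#'   ([coef()], [vcov()], [predict.mutual_fit()], [fitted()],
#'   [residuals()], [summary.mutual_fit()], [simulate.mutual_fit()],
#'   [plot.mutual_fit()]) apply.
#' @seealso [classify_mutual_effect()] to turn estimates into qualitative
#'   effect labels, [generate_endpoint_table()] to simulate input data.
#' @examples
#' p <- energy_params(g_X = 300, g_cat = c(N1 = 200, N2 = 120), g_an = 100)
#' eff <- two_degradable_effects(m_cat_1 = 0.004)
#' des <- endpoint_design(measured_amounts = seq(0, 240, 40),
#'                        base_amounts = c(0, 80, 160), noise_cv = 0, seed = 1)
#' tab <- generate_endpoint_table(p, des, effects = eff)
#' fit <- fit_mutual_effects(tab$endpoints, model = "two_degradable")
#' coef(fit)
#' @export
fit_mutual_effects <- function(endpoints,
                               model = c("two_degradable", "precursor"),
                               q_req = 0.02, n_starts = 5L, seed = 1L,
                               start = NULL) {
  model <- match.arg(model)
  stopifnot(is.data.frame(endpoints))
  dB <- endpoints$delta_B_mean_ug %||% endpoints$delta_B_ug
  if (is.null(dB)) stop("endpoints must contain delta_B_mean_ug or delta_B_ug")
  x1 <- endpoints$measured_amount_ug
  x2 <- endpoints$base_amount_ug
  if (is.null(x1) || is.null(x2))
    stop("endpoints must contain measured_amount_ug and base_amount_ug")
  keep <- is.finite(dB) & is.finite(x1) & is.finite(x2)
  dB <- dB[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  if (length(unique(x2)) < 2L)
    stop(errorCondition(
      paste0("design has a single base amount: interaction coefficients are ",
             "confounded with the single-nutrient yields and cannot be ",
             "identified; provide endpoints at >= 2 base amounts"),
      class = c("multiyield_identifiability_error", "error")))
  if (length(unique(x1)) < 2L) stop("need >= 2 distinct measured amounts")
  min_n <- if (model == "two_degradable") 8L else 10L
  if (length(dB) < min_n)
    stop("need at least ", min_n, " endpoint rows for the ", model, " model")

  if (model == "two_degradable") {
    predict_fun <- function(th, N1, N2) {
      den <- 1 + th[["alpha1"]] * N1 + th[["alpha2"]] * N2
      ifelse(den > 0,
             (th[["Y1"]] * N1 + th[["Y2"]] * N2 + th[["delta"]] * N1 * N2) / den,
             NA_real_)
    }
    # OLS initialisation of the numerator, anabolic coefficients start at 0
    ols <- stats::lm(dB ~ 0 + x1 + x2 + I(x1 * x2))
    cf <- stats::coef(ols)
    base_start <- c(Y1 = max(unname(cf[1]), 1e-4),
                    Y2 = max(unname(cf[2]), 1e-4),
                    delta = unname(cf[3]), alpha1 = 0, alpha2 = 0)
    lower <- c(Y1 = 1e-12, Y2 = 1e-12, delta = -Inf,
               alpha1 = -0.9 / max(x1, 1), alpha2 = -0.9 / max(x2, 1))
  } else {
    if (q_req <= 0) stop("q_req must be > 0 for the precursor model")
    predict_fun <- function(th, N1, N2) {
      # N1 = precursor amount M (measured), N2 = degradable nutrient N (base)
      vapply(seq_along(N1), function(i) {
        tryCatch(.solve_precursor_reduced(th[["y_N"]], th[["m_cat"]],
                                          th[["beta_M"]], th[["alpha_N"]],
                                          th[["beta_MN"]],
                                          N = N2[i], M = N1[i],
                                          q_req = q_req)$delta_B,
                 error = function(e) NA_real_)
      }, 0)
    }
    y0 <- {
      at0 <- x1 == 0 & x2 > 0
      if (any(at0)) stats::median(dB[at0] / x2[at0]) else
        stats::median(dB[x2 > 0] / x2[x2 > 0])
    }
    base_start <- c(y_N = max(y0, 1e-4), m_cat = 0, beta_M = 0.05,
                    alpha_N = 0, beta_MN = 0)
    lower <- c(y_N = 1e-12, m_cat = -0.99, beta_M = -Inf,
               alpha_N = -0.9 / max(x2, 1), beta_MN = -Inf)
  }
  if (!is.null(start)) {
    stopifnot(all(names(base_start) %in% names(start)))
    base_start <- start[names(base_start)]
  }

  starts <- .multistart_values(base_start, n_starts, seed, model)
  penal <- 10 * max(abs(dB), 1)
  resid_fun <- function(th) {
    pr <- predict_fun(th, x1, x2)
    bad <- !is.finite(pr)
    pr[bad] <- -penal
    dB - pr
  }
  best <- NULL; n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("nonlinear least squares failed to converge from any of the ",
         n_starts, " starts")

  th <- stats::coef(best)
  pred <- predict_fun(th, x1, x2)
  res <- dB - pred
  dfres <- length(dB) - length(th)
  sigma2 <- sum(res^2) / max(dfres, 1L)
  # nls.lm hessian is the Gauss-Newton J'J; vcov = sigma^2 (J'J)^-1
  vc <- tryCatch(sigma2 * solve(best$hessian),
                 error = function(e) matrix(NA_real_, length(th), length(th)))
  dimnames(vc) <- list(names(th), names(th))
  se <- sqrt(pmax(diag(vc), 0))

  structure(list(coefficients = th, se = se, vcov = vc,
                 fitted.values = pred, residuals = res,
                 sse = sum(res^2), sigma = sqrt(sigma2), df.residual = dfres,
                 model = model, q_req = if (model == "precursor") q_req else NA_real_,
                 data = data.frame(measured_amount_ug = x1,
                                   base_amount_ug = x2, delta_B_ug = dB),
                 n_starts_converged = n_conv,
                 call = match.call()),
            class = "mutual_fit")
}

# deterministic multistart: base start, sign probes for the catabolic
# coupling, then log-uniform +/-50% perturbations under the given seed
.multistart_values <- function(base_start, n_starts, seed, model) {
  starts <- list(base_start)
  if (model == "precursor" && n_starts >= 3L) {
    s <- base_start; s[["m_cat"]] <- -0.5; starts <- c(starts, list(s))
    s <- base_start; s[["m_cat"]] <- 0.5; starts <- c(starts, list(s))
  }
  need <- n_starts - length(starts)
  if (need > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    for (k in seq_len(need)) {
      s <- base_start
      fac <- exp(stats::runif(length(s), log(0.5), log(1.5)))
      s <- s * fac
      zero <- abs(base_start) < 1e-10
      s[zero] <- stats::runif(sum(zero), -1e-3, 1e-3)
      starts <- c(starts, list(s))
    }
  }
  starts[seq_len(min(n_starts, length(starts)))]
}

#' Classify mutual effects from a fitted model
#'
#' Deterministically maps fitted mutual-effect coefficients to qualitative
#' labels: a coefficient more than two standard errors above zero is
#' `"positive"`, more than two below is `"negative"`, anything else `"none"`.
#' For the two-degradable model the catabolic label comes from the reduced
#' interaction `delta` and the anabolic label from the reduced `alpha`
#' coefficients (the one with the larger |z| decides when both are
#' significant); for the precursor model the catabolic label comes from
#' `m_cat`, the biosynthesis label from the interaction `beta_MN`
#' (`"positive"` or `"none"`), and the anabolic label from `alpha_N`.
#'
#' @param fit A [fit_mutual_effects()] object.
#' @param z_threshold Significance threshold in standard errors (default 2).
#' @return Object of class `"effect_classification"`: `catabolic`,
#'   `biosynthesis`, `anabolic` labels plus an `evidence` data frame with
#'   estimates, standard errors and z-values. When the covariance was not
#'   available the labels are reported with `confidence = FALSE`.
#' @export
classify_mutual_effect <- function(fit, z_threshold = 2) {
  stopifnot(inherits(fit, "mutual_fit"))
  th <- fit$coefficients; se <- fit$se
  have_cov <- all(is.finite(se)) && all(se >= 0)
  zval <- function(nm) if (have_cov && se[[nm]] > 0) th[[nm]] / se[[nm]] else NA_real_
  lab3 <- function(z) {
    if (!is.finite(z)) return("none")
    if (z > z_threshold) "positive" else if (z < -z_threshold) "negative" else "none"
  }
  if (fit$model == "two_degradable") {
    z_cat <- zval("delta")
    z_a1 <- zval("alpha1"); z_a2 <- zval("alpha2")
    z_an <- if (!is.finite(z_a1)) z_a2
            else if (!is.finite(z_a2)) z_a1
            else if (abs(z_a1) >= abs(z_a2)) z_a1 else z_a2
    catabolic <- lab3(z_cat); anabolic <- lab3(z_an); biosynthesis <- "none"
    ev <- data.frame(effect = c("catabolic", "anabolic_1", "anabolic_2"),
                     coefficient = c("delta", "alpha1", "alpha2"),
                     estimate = unname(th[c("delta", "alpha1", "alpha2")]),
                     se = unname(se[c("delta", "alpha1", "alpha2")]),
                     z = c(z_cat, z_a1, z_a2))
  } else {
    z_cat <- zval("m_cat"); z_b <- zval("beta_MN"); z_an <- zval("alpha_N")
    catabolic <- lab3(z_cat)
    biosynthesis <- if (is.finite(z_b) && z_b > z_threshold) "positive" else "none"
    anabolic <- lab3(z_an)
    ev <- data.frame(effect = c("catabolic", "biosynthesis", "anabolic"),
                     coefficient = c("m_cat", "beta_MN", "alpha_N"),
                     estimate = unname(th[c("m_cat", "beta_MN", "alpha_N")]),
                     se = unname(se[c("m_cat", "beta_MN", "alpha_N")]),
                     z = c(z_cat, z_b, z_an))
  }
  structure(list(catabolic = catabolic, biosynthesis = biosynthesis,
                 anabolic = anabolic, confidence = have_cov,
                 z_threshold = z_threshold, evidence = ev),
            class = "effect_classification")
}

#' @export
print.effect_classification <- function(x, ...) {
  cat("Mutual-effect classification",
      if (!x$confidence) "(confidence withheld: no covariance)" else "", "\n")
  cat("  catabolic   :", x$catabolic, "\n")
  cat("  biosynthesis:", x$biosynthesis, "\n")
  cat("  anabolic    :", x$anabolic, "\n")
  print(x$evidence, row.names = FALSE, digits = 4)
  invisible(x)
}
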