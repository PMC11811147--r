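#' @export
print.mutual_fit <- function(x, ...) {
  cat("Expanded black-box mutual-effect model (", x$model, ")\n", sep = "")
  cat("Reduced coefficients:\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("Residual SSE %.5g on %d degrees of freedom (%d points)\n",
              x$sse, x$df.residual, nrow(x$data)))
  invisible(x)
}

#' Summarise a fitted mutual-effect model
#'
#' @param object A [fit_mutual_effects()] object.
#' @param ... Unused.
#' @return Object of class `"summary.mutual_fit"` with a coefficient table
#'   (estimate, standard error, z-value), residual summary and the
#'   qualitative [classify_mutual_effect()] labels.
#' @export
summary.mutual_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = object$coefficients / ifelse(object$se > 0,
                                                        object$se, NA_real_))
  structure(list(fit = object, coefficients = tab,
                 classification = classify_mutual_effect(object)),
            class = "summary.mutual_fit")
}

#' @export
print.summary.mutual_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficient table:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\n")
  print(x$classification)
  invisible(x)
}

#' @export
coef.mutual_fit <- function(object, ...) object$coefficients

#' @export
vcov.mutual_fit <- function(object, ...) object$vcov

#' @export
fitted.mutual_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mutual_fit <- function(object, ...) object$residuals

#' Predict produced biomass from a fitted mutual-effect model
#'
#' Evaluates the fitted reduced model on new measured/base amount pairs.
#'
#' @param object A [fit_mutual_effects()] object.
#' @param newdata Data frame with columns `measured_amount_ug` and
#'   `base_amount_ug`; defaults to the fitted design.
#' @param ... Unused.
#' @return Numeric vector of predicted produced biomass, ug.
#' @export
predict.mutual_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  stopifnot(is.data.frame(newdata),
            all(c("measured_amount_ug", "base_amount_ug") %in% names(newdata)))
  th <- object$coefficients
  N1 <- newdata$measured_amount_ug
  N2 <- newdata$base_amount_ug
  if (object$model == "two_degradable") {
    den <- 1 + th[["alpha1"]] * N1 + th[["alpha2"]] * N2
    if (any(den <= 0))
      stop_validity("fitted model invalid at requested amounts (denominator <= 0)")
    (th[["Y1"]] * N1 + th[["Y2"]] * N2 + th[["delta"]] * N1 * N2) / den
  } else {
    vapply(seq_along(N1), function(i)
      .solve_precursor_reduced(th[["y_N"]], th[["m_cat"]], th[["beta_M"]],
                               th[["alpha_N"]], th[["beta_MN"]],
                               N = N2[i], M = N1[i],
                               q_req = object$q_req)$delta_B, 0)
  }
}

#' Simulate endpoint data from a fitted mutual-effect model
#'
#' Draws replicate produced-biomass tables from the fitted model on its own
#' design, with multiplicative Gaussian noise, mirroring the measurement
#' model of the synthetic-data generators.
#'
#' @param object A [fit_mutual_effects()] object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   defaults to the fit's residual sigma relative to the mean fitted value.
#' @param ... Unused.
#' @return Data frame with `nsim` columns (`sim_1`, ...), one row per design
#'   point.
#' @export
simulate.mutual_fit <- function(object, nsim = 1, seed = NULL,
                                noise_cv = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- object$fitted.values
  if (is.null(noise_cv)) {
    mbar <- mean(abs(mu[mu != 0]))
    noise_cv <- if (is.finite(mbar) && mbar > 0) object$sigma / mbar else 0
  }
  out <- as.data.frame(lapply(seq_len(nsim), function(k)
    mu * pmax(1 + stats::rnorm(length(mu), 0, noise_cv), 0.1)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted mutual-effect model against its data
#'
#' Produced biomass against the measured amount, one colour per base amount,
#' with the fitted model drawn as lines over a fine grid.
#'
#' @param x A [fit_mutual_effects()] object.
#' @param n_grid Number of grid points per fitted curve.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mutual_fit <- function(x, n_grid = 80L, ...) {
  d <- x$data
  bases <- sort(unique(d$base_amount_ug))
  cols <- grDevices::hcl.colors(max(length(bases), 2L), "Dark 2")
  graphics::plot(d$measured_amount_ug, d$delta_B_ug,
                 col = cols[match(d$base_amount_ug, bases)], pch = 19,
                 xlab = "measured nutrient amount (ug)",
                 ylab = "produced biomass (ug)", ...)
  xg <- seq(min(d$measured_amount_ug), max(d$measured_amount_ug),
            length.out = n_grid)
  for (k in seq_along(bases)) {
    yg <- predict(x, data.frame(measured_amount_ug = xg,
                                base_amount_ug = bases[k]))
    graphics::lines(xg, yg, col = cols[k])
  }
  graphics::legend("topleft", legend = paste("base", bases, "ug"),
                   col = cols[seq_along(bases)], lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
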