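#' Map the qualitative solution space of the expanded model
#'
#' Sweeps the measured-nutrient amount at a fixed base amount for each
#' supplied mutual-effect setting, compares the produced-biomass curve with
#' the zero-coefficient (additive) reference, and labels the regime of each
#' setting:
#'
#' * `"additive"` — the curve coincides with the zero-coefficient curve
#'   (maximum relative deviation below `tol_additive`);
#' * `"non_monotone"` — the curve has a strict local extremum in the
#'   interior of the sweep;
#' * `"yield_increase"` / `"yield_decrease"` — the terminal slope (ordinary
#'   least squares over the last 20 percent of the sweep) lies above or
#'   below the additive curve's terminal slope;
#' * `"invalid"` — the model violates a validity constraint somewhere on the
#'   sweep (reported, never skipped silently).
#'
#' @param params An [energy_params()] object.
#' @param effects_list List of [two_degradable_effects()] and/or
#'   [precursor_effects()] objects (one regime label each).
#' @param design List with `measured_amounts` (the sweep grid, ug) and
#'   `base_amount` (single fixed amount, ug).
#' @param spec A [precursor_spec()]; required when `effects_list` contains
#'   precursor settings.
#' @param tol_additive Relative tolerance for the additive label.
#' @return Data frame of class `"regime_map"`: one row per setting with the
#'   coefficient values, the model variant and the regime `label`.
#' @examples
#' p <- energy_params(g_X = 300, g_cat = c(N1 = 200, N2 = 120), g_an = 100)
#' map_solution_space(p, list(two_degradable_effects(),
#'                            two_degradable_effects(m_cat_1 = 0.01)),
#'                    design = list(measured_amounts = seq(0, 240, 20),
#'                                  base_amount = 160))
#' @export
map_solution_space <- function(params, effects_list, design, spec = NULL,
                               tol_additive = 1e-9) {
  stopifnot(inherits(params, "energy_params"), is.list(effects_list),
            length(effects_list) >= 1L,
            is.list(design), !is.null(design$measured_amounts),
            !is.null(design$base_amount))
  xs <- sort(unique(design$measured_amounts))
  if (length(xs) < 5L) stop("need >= 5 measured amounts for a regime sweep")
  nb <- design$base_amount
  sweep_curve <- function(eff) {
    if (inherits(eff, "two_degradable_effects")) {
      produced_biomass_two_degradable(params, eff, N1 = xs, N2 = nb)
    } else if (inherits(eff, "precursor_effects")) {
      if (is.null(spec)) stop("precursor settings require a precursor_spec")
      vapply(xs, function(m)
        produced_biomass_precursor(params, eff, spec, N = nb, M = m)$delta_B, 0)
    } else stop("unsupported effects object of class ", class(eff)[1])
  }
  ref_for <- function(eff) {
    if (inherits(eff, "two_degradable_effects")) sweep_curve(two_degradable_effects())
    else sweep_curve(precursor_effects())
  }
  terminal_slope <- function(curve) {
    k <- max(2L, ceiling(0.2 * length(xs)))
    idx <- (length(xs) - k + 1L):length(xs)
    unname(stats::coef(stats::lm(curve[idx] ~ xs[idx]))[2])
  }
  label_one <- function(eff) {
    curve <- tryCatch(sweep_curve(eff), multiyield_validity_error = function(e) NULL)
    if (is.null(curve)) return("invalid")
    ref <- ref_for(eff)
    scale <- max(abs(ref), 1e-12)
    if (max(abs(curve - ref)) <= tol_additive * scale) return("additive")
    d <- diff(curve)
    tol_d <- 1e-12 * max(abs(curve), 1)
    if (any(d[-length(d)] > tol_d & d[-1] < -tol_d) ||
        any(d[-length(d)] < -tol_d & d[-1] > tol_d)) return("non_monotone")
    ds <- terminal_slope(curve) - terminal_slope(ref)
    if (abs(ds) <= tol_additive * max(abs(terminal_slope(ref)), 1e-12)) {
      # same terminal slope but different curve: decide by mean offset
      if (mean(curve - ref) > 0) "yield_increase" else "yield_decrease"
    } else if (ds > 0) "yield_increase" else "yield_decrease"
  }
  rows <- lapply(effects_list, function(eff) {
    cf <- as.data.frame(unclass(eff))
    cf$model <- if (inherits(eff, "precursor_effects")) "precursor" else "two_degradable"
    cf$label <- label_one(eff)
    cf
  })
  nm <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("regime_map", "data.frame"))
}

#' @export
print.regime_map <- function(x, ...) {
  cat("Regime map (", nrow(x), " coefficient settings)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
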