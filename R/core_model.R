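#' Overall biomass yield of a single nutrient
#'
#' The black-box prediction of the overall biomass yield: the catabolic energy
#' release per gram of nutrient divided by the total dissipation and anabolic
#' cost per gram of biomass. Without a precursor decomposition this is
#' `g_cat / (g_X + g_an)`. When `m_utl` is supplied the anabolic cost is split
#' into its biosynthesis-excluded part plus the residual biosynthesis cost of
#' the precursor, `g_cat / (g_X + g_an_excl + g_bsyn * (1 - m_utl))`, so that
#' external precursor supply (larger `m_utl`) raises the yield.
#'
#' @param params An [energy_params()] object.
#' @param nutrient_id Name of the nutrient in `params$g_cat`. Defaults to the
#'   first entry.
#' @param m_utl Optional precursor utilisation fraction in \[0, 1\]. When
#'   missing, the undecomposed yield `g_cat / (g_X + g_an)` is returned.
#' @return Overall biomass yield, g biomass per g nutrient (strictly positive).
#' @examples
#' p <- energy_params(g_X = 300, g_cat = c(glc = 200), g_an = 100)
#' overall_yield_single(p)          # 0.5
#' @export
overall_yield_single <- function(params, nutrient_id = names(params$g_cat)[1],
                                 m_utl = NULL) {
  stopifnot(inherits(params, "energy_params"))
  if (!nutrient_id %in% names(params$g_cat))
    stop("unknown nutrient id: ", nutrient_id)
  g_cat <- params$g_cat[[nutrient_id]]
  if (is.null(m_utl)) return(g_cat / (params$g_X + params$g_an))
  stopifnot(is.numeric(m_utl), length(m_utl) == 1L)
  if (!is.finite(m_utl) || m_utl < 0 || m_utl > 1)
    stop_validity("m_utl must lie in [0, 1]")
  g_cat / (params$g_X + params$g_an_excl + params$g_bsyn * (1 - m_utl))
}

#' Produced biomass from a single nutrient at a given yield
#'
#' The linear produced-biomass relation of the black-box model:
#' `delta_B = Y * N`.
#'
#' @param yield_Y Overall biomass yield (ug biomass per ug nutrient), >= 0.
#' @param amount_N Initial nutrient amount, ug, >= 0.
#' @return Produced biomass, ug.
#' @export
produced_biomass_linear <- function(yield_Y, amount_N) {
  stopifnot(is.numeric(yield_Y), is.numeric(amount_N))
  if (any(!is.finite(yield_Y)) || any(yield_Y < 0))
    stop_validity("yield_Y must be finite and >= 0")
  if (any(!is.finite(amount_N)) || any(amount_N < 0))
    stop_validity("amount_N must be finite and >= 0")
  yield_Y * amount_N
}

#' Produced biomass from several non-interacting nutrients
#'
#' Without mutual effects the produced biomass is the linear sum of the
#' biomass gained from each available nutrient,
#' `delta_B = sum_i Y_i * N_i`, with each yield computed by
#' [overall_yield_single()].
#'
#' @param params An [energy_params()] object.
#' @param doses Named numeric vector mapping nutrient ids to initial amounts
#'   (ug). Names must be present in `params$g_cat`.
#' @return Produced biomass, ug.
#' @export
produced_biomass_additive <- function(params, doses) {
  stopifnot(inherits(params, "energy_params"), is.numeric(doses))
  if (!length(doses)) stop("empty dose map")
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop("doses must be a named vector of nutrient amounts")
  unknown <- setdiff(names(doses), names(params$g_cat))
  if (length(unknown)) stop("unknown nutrient id: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(doses)) || any(doses < 0))
    stop_validity("doses must be finite and >= 0")
  ys <- vapply(names(doses), function(id) overall_yield_single(params, id), 0)
  sum(ys * doses)
}

#' Produced biomass for two degradable nutrients with mutual effects
#'
#' Closed-form produced biomass of the expanded black-box model for two
#' degradable nutrients with phenomenological mutual effects:
#' \deqn{\Delta B = \frac{g_{cat,1} N_1 + g_{cat,2} N_2 +
#'   \Delta m_{CAT} N_1 N_2}{g_X + g_{an} f_{an}(N_1, N_2)}}
#' with \eqn{\Delta m_{CAT} = g_{cat,1} m_{cat,1} + g_{cat,2} m_{cat,2}} and
#' \eqn{f_{an} = 1 + m_{an,1} N_1 + m_{an,2} N_2}. With all four coefficients
#' zero this reduces exactly to the additive sum
#' [produced_biomass_additive()].
#'
#' @param params An [energy_params()] object with at least two `g_cat`
#'   entries (the first two are nutrient 1 and nutrient 2 unless
#'   `nutrient_ids` is given).
#' @param effects A [two_degradable_effects()] object.
#' @param N1,N2 Initial amounts of nutrients 1 and 2, ug, >= 0. Vectorised.
#' @param nutrient_ids Length-2 character vector naming nutrients 1 and 2 in
#'   `params$g_cat`.
#' @return Produced biomass, ug (vectorised over `N1`/`N2`).
#' @export
produced_biomass_two_degradable <- function(params, effects, N1, N2,
                                            nutrient_ids = names(params$g_cat)[1:2]) {
  stopifnot(inherits(params, "energy_params"),
            inherits(effects, "two_degradable_effects"),
            length(nutrient_ids) == 2L)
  if (anyNA(nutrient_ids) || !all(nutrient_ids %in% names(params$g_cat)))
    stop("params$g_cat must contain both nutrient ids")
  if (any(!is.finite(N1)) || any(N1 < 0) || any(!is.finite(N2)) || any(N2 < 0))
    stop_validity("nutrient amounts must be finite and >= 0")
  g1 <- params$g_cat[[nutrient_ids[1]]]
  g2 <- params$g_cat[[nutrient_ids[2]]]
  dm_cat <- g1 * effects$m_cat_1 + g2 * effects$m_cat_2
  f_an <- 1 + effects$m_an_1 * N1 + effects$m_an_2 * N2
  if (any(f_an <= 0))
    stop_validity("f_an <= 0 at these amounts: model invalid over this design")
  denom <- params$g_X + params$g_an * f_an
  if (any(denom <= 0))
    stop_validity("non-positive denominator g_X + g_an * f_an: model invalid at these amounts")
  (g1 * N1 + g2 * N2 + dm_cat * N1 * N2) / denom
}

#' Precursor utilisation fraction
#'
#' The ratio of externally available biomass precursor to the amount required
#' to generate the produced biomass, capped at 1 (precursor in excess fully
#' alleviates the biosynthesis cost):
#' `m_utl = min(1, M_avail / (q_req * delta_B))`.
#'
#' @param M_avail Available precursor amount, ug, >= 0.
#' @param spec A [precursor_spec()] object (requirement `q_req`, ug/ug).
#' @param delta_B Produced biomass, ug, >= 0. When `delta_B` is 0 with any
#'   precursor available the entire (vanishing) need is covered and the value
#'   is 1; with `M_avail = 0` it is 0.
#' @return Utilisation fraction in \[0, 1\].
#' @export
m_utl_value <- function(M_avail, spec, delta_B) {
  stopifnot(inherits(spec, "precursor_spec"))
  if (any(!is.finite(M_avail)) || any(M_avail < 0))
    stop_validity("M_avail must be finite and >= 0")
  if (any(!is.finite(delta_B)) || any(delta_B < 0))
    stop_validity("delta_B must be finite and >= 0")
  ifelse(M_avail == 0, 0,
         ifelse(delta_B == 0, 1, pmin(1, M_avail / (spec$q_req * delta_B))))
}

# --- internal reduced precursor solver -------------------------------------
#
# The precursor balance divided by G_A0 = g_X + g_an_excl + g_bsyn depends on
# the magnitudes only through five reduced parameters:
#   y_N     = g_cat / G_A0                         (base yield)
#   m_cat                                          (unchanged, dimensionless)
#   beta_M  = (g_bsyn - g_an_excl * m_an_M) / G_A0 (M'-gain of the linear term)
#   alpha_N = (g_an_excl*m_an_N + g_bsyn*m_bsyn)/G_A0  (per ug N)
#   beta_MN = g_bsyn * m_bsyn / G_A0               (per ug N, N x M_utl term)
# Unsaturated branch (M' = M/q_req, M_utl = M'/dB <= 1):
#   A dB^2 - b dB - cc = 0,  A = 1 + alpha_N N,
#   b = N y_N + (beta_M + beta_MN N) M',  cc = N y_N m_cat M'
# Saturated branch (M_utl = 1): dB = N y_N (1+m_cat) / (A - beta_M - beta_MN N)
.solve_precursor_reduced <- function(y_N, m_cat, beta_M, alpha_N, beta_MN,
                                     N, M, q_req) {
  A <- 1 + alpha_N * N
  if (A <= 0) stop_validity("G_A <= 0: model invalid at this N")
  Mp <- M / q_req
  beta <- beta_M + beta_MN * N
  b <- N * y_N + beta * Mp
  cc <- N * y_N * m_cat * Mp
  tolc <- 1e-14 * max(abs(b), abs(N * y_N), 1)

  unsat <- NULL
  if (abs(cc) <= tolc) {
    dB <- b / A
    if (dB >= 0)
      unsat <- list(delta_B = dB, discriminant = b^2, root_used = "linear")
  } else {
    disc <- b^2 + 4 * A * cc
    if (disc >= 0) {
      r <- (b + sqrt(disc)) / (2 * A)  # larger root, continuous with M -> 0
      if (r > 0) {
        other <- (b - sqrt(disc)) / (2 * A)
        unsat <- list(delta_B = r, discriminant = disc,
                      root_used = if (other > 0) "larger" else "only_positive")
      }
    }
  }
  if (!is.null(unsat)) {
    m_utl <- if (unsat$delta_B > 0) Mp / unsat$delta_B else if (Mp > 0) Inf else 0
    if (m_utl <= 1)
      return(structure(list(delta_B = unsat$delta_B, m_utl = m_utl,
                            branch = "unsaturated",
                            discriminant = unsat$discriminant,
                            root_used = unsat$root_used),
                       class = "biomass_solution"))
  }
  # saturated branch: M_utl = 1, biosynthesis cost fully alleviated
  denom <- A - beta_M - beta_MN * N
  if (denom <= 0)
    stop_validity("saturated-branch denominator <= 0: model invalid")
  dB <- N * y_N * (1 + m_cat) / denom
  if (dB < 0) stop_validity("no positive produced-biomass solution")
  if (Mp < dB * (1 - 1e-9))
    stop_validity(paste0("no consistent solution: unsaturated branch invalid and ",
                         "available precursor below saturated-branch requirement"))
  structure(list(delta_B = dB, m_utl = 1, branch = "saturated",
                 discriminant = NA_real_, root_used = "linear"),
            class = "biomass_solution")
}

.reduce_precursor <- function(params, effects) {
  G_A0 <- params$g_X + params$g_an_excl + params$g_bsyn
  list(G_A0 = G_A0,
       m_cat = effects$m_cat,
       beta_M = (params$g_bsyn - params$g_an_excl * effects$m_an_M) / G_A0,
       alpha_N = (params$g_an_excl * effects$m_an_N +
                  params$g_bsyn * effects$m_bsyn) / G_A0,
       beta_MN = params$g_bsyn * effects$m_bsyn / G_A0)
}

#' Produced biomass for a degradable nutrient plus a biomass precursor
#'
#' Closed-form solution of the expanded black-box model when the second
#' nutrient is a non-degradable biomass precursor. On the unsaturated branch
#' (`M_utl < 1`, all available precursor incorporated, `M' = M / q_req`) the
#' energy balance is quadratic in the produced biomass:
#' \deqn{G_A \Delta B^2 - \Delta B \left[N g_{cat} - g_{an}^{excl} m_{an}^M M'
#'   + g_{bsyn} (1 + m_{bsyn} N) M'\right] - N g_{cat} m_{cat} M' = 0}
#' with \eqn{G_A = g_X + g_{an}^{excl} (1 + m_{an}^N N) +
#' g_{bsyn} (1 + m_{bsyn} N)}. The larger real root (the branch continuous
#' with the `M -> 0` limit, where the roots are 0 and `N g_cat / G_A`) is
#' accepted if its implied utilisation `M'/dB` does not exceed 1; otherwise
#' the saturated branch (`M_utl = 1`, biosynthesis cost fully alleviated) is
#' solved, which is linear. If the unsaturated quadratic has no real root the
#' saturated branch is used when the available precursor covers its
#' requirement; otherwise a validity error is raised.
#'
#' @param params An [energy_params()] object with `g_an_excl`/`g_bsyn` set.
#' @param effects A [precursor_effects()] object.
#' @param spec A [precursor_spec()] object.
#' @param N Degradable nutrient amount, ug, >= 0.
#' @param M Precursor amount, ug, >= 0.
#' @param nutrient_id Name of the degradable nutrient in `params$g_cat`.
#' @return An object of class `"biomass_solution"`: list with `delta_B` (ug),
#'   `m_utl` (in \[0,1\]), `branch` (`"unsaturated"` or `"saturated"`),
#'   `discriminant` (of the quadratic, `NA` on the saturated branch) and
#'   `root_used` (`"larger"`, `"only_positive"` or `"linear"`).
#' @seealso [solve_energy_balance_numeric()] for the independent numeric
#'   solver of the same balance.
#' @export
produced_biomass_precursor <- function(params, effects, spec, N, M,
                                       nutrient_id = names(params$g_cat)[1]) {
  stopifnot(inherits(params, "energy_params"),
            inherits(effects, "precursor_effects"),
            inherits(spec, "precursor_spec"),
            is.numeric(N), length(N) == 1L, is.numeric(M), length(M) == 1L)
  if (!nutrient_id %in% names(params$g_cat))
    stop("unknown nutrient id: ", nutrient_id)
  if (!is.finite(N) || N < 0 || !is.finite(M) || M < 0)
    stop_validity("N and M must be finite and >= 0")
  red <- .reduce_precursor(params, effects)
  .solve_precursor_reduced(params$g_cat[[nutrient_id]] / red$G_A0,
                           red$m_cat, red$beta_M, red$alpha_N, red$beta_MN,
                           N, M, spec$q_req)
}

#' @export
print.biomass_solution <- function(x, ...) {
  cat(sprintf("Produced biomass: %.6g ug (M_utl = %.4g, %s branch, root: %s)\n",
              x$delta_B, x$m_utl, x$branch, x$root_used))
  invisible(x)
}

#' Numeric solver of the precursor energy balance
#'
#' Independent numeric solution of the implicit energy balance
#' \deqn{N g_{cat} f_{cat}(M_{utl}) = \Delta B \left[g_X +
#'   g_{an}^{excl} f_{an}(N, M_{utl}) + g_{bsyn} f_{bsyn}(N)
#'   (1 - M_{utl})\right]}
#' with \eqn{M_{utl} = \min(1, M / (q_{req} \Delta B))}, by sign-scan plus
#' bisection for the largest root of the balance residual. Serves as an
#' oracle for the closed-form [produced_biomass_precursor()]; the two agree
#' to solver tolerance wherever both converge.
#'
#' @inheritParams produced_biomass_precursor
#' @param tol Relative convergence tolerance of the bisection.
#' @param n_scan Number of grid points in the initial sign scan.
#' @return Produced biomass, ug.
#' @export
solve_energy_balance_numeric <- function(params, effects, spec, N, M,
                                         nutrient_id = names(params$g_cat)[1],
                                         tol = 1e-12, n_scan = 2000L) {
  stopifnot(inherits(params, "energy_params"),
            inherits(effects, "precursor_effects"),
            inherits(spec, "precursor_spec"))
  if (!is.finite(N) || N < 0 || !is.finite(M) || M < 0)
    stop_validity("N and M must be finite and >= 0")
  g_cat <- params$g_cat[[nutrient_id]]
  Mp <- M / spec$q_req
  bal <- function(x) {
    u <- if (Mp == 0) 0 else min(1, Mp / x)
    supply <- N * g_cat * (1 + effects$m_cat * u)
    demand <- x * (params$g_X +
                   params$g_an_excl * (1 + effects$m_an_N * N + effects$m_an_M * u) +
                   params$g_bsyn * (1 + effects$m_bsyn * N) * (1 - u))
    supply - demand
  }
  if (N == 0 && Mp == 0) return(0)
  hi <- 2 * (N * g_cat * (1 + abs(effects$m_cat)) +
             params$g_bsyn * (1 + abs(effects$m_bsyn) * N) * max(Mp, 1)) /
        params$g_X + Mp + 1
  xs <- seq(hi, hi * 1e-10, length.out = n_scan)
  vals <- vapply(xs, bal, 0)
  ipos <- which(vals > 0)[1]
  if (is.na(ipos))
    stop("numeric energy-balance solver did not bracket a root (no solution found)")
  if (ipos == 1L)
    stop("numeric energy-balance solver: upper bound too small")
  r <- stats::uniroot(bal, lower = xs[ipos], upper = xs[ipos - 1L],
                      tol = tol * max(xs[ipos], 1))
  r$root
}
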