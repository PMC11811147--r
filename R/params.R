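#' Gibbs energy dissipation parameters of the black-box growth model
#'
#' Bundles the magnitudes of the Gibbs energy dissipation terms that define the
#' black-box energy balance of chemotrophic growth: an overall dissipation per
#' unit biomass, a catabolic energy release per unit of each degradable
#' nutrient, and anabolic costs per unit biomass, optionally split into a
#' biosynthesis-excluded part and the biosynthesis cost of one biomass
#' precursor.
#'
#' All energies are stored as non-negative magnitudes, so the energy balance
#' reads "catabolic supply = overall dissipation + anabolic costs" and the
#' single-nutrient overall biomass yield is `g_cat / (g_X + g_an)`. Under the
#' usual signed thermodynamic convention the catabolic and overall dissipation
#' terms are negative (energy releasing) and the anabolic terms positive; the
#' magnitudes used here are the absolute values of those quantities.
#'
#' @param g_X Overall Gibbs energy dissipation magnitude, kJ per g biomass.
#'   Must be strictly positive.
#' @param g_cat Named numeric vector of catabolic energy magnitudes, kJ per g
#'   nutrient, one entry per degradable nutrient. All entries strictly
#'   positive.
#' @param g_an Anabolic dissipation cost, kJ per g biomass.
#' @param g_an_excl Anabolic cost excluding biosynthesis of the precursor of
#'   interest, kJ per g biomass. Must not exceed `g_an`. Defaults to `g_an`
#'   (no precursor split).
#' @param g_bsyn Dissipation cost of synthesising the biomass precursor, kJ
#'   per g biomass. Defaults to `g_an - g_an_excl`.
#'
#' @return An object of class `"energy_params"`: a list with elements `g_X`,
#'   `g_cat`, `g_an`, `g_an_excl`, `g_bsyn`.
#' @seealso [overall_yield_single()], [produced_biomass_two_degradable()],
#'   [produced_biomass_precursor()]
#' @examples
#' energy_params(g_X = 300, g_cat = c(glc = 200, xyl = 180), g_an = 100)
#' @export
energy_params <- function(g_X, g_cat, g_an, g_an_excl = g_an,
                          g_bsyn = g_an - g_an_excl) {
  stopifnot(is.numeric(g_X), length(g_X) == 1L,
            is.numeric(g_cat), length(g_cat) >= 1L,
            is.numeric(g_an), length(g_an) == 1L,
            is.numeric(g_an_excl), length(g_an_excl) == 1L,
            is.numeric(g_bsyn), length(g_bsyn) == 1L)
  if (!all(is.finite(c(g_X, g_cat, g_an, g_an_excl, g_bsyn))))
    stop_validity("energy parameters must be finite")
  if (g_X <= 0) stop_validity("g_X must be > 0")
  if (any(g_cat <= 0)) stop_validity("every g_cat entry must be > 0")
  if (g_an < 0 || g_an_excl < 0 || g_bsyn < 0)
    stop_validity("anabolic and biosynthesis costs must be >= 0")
  if (g_an_excl > g_an + 1e-12 * max(1, g_an))
    stop_validity("g_an_excl must not exceed g_an")
  if (is.null(names(g_cat)))
    names(g_cat) <- paste0("N", seq_along(g_cat))
  structure(list(g_X = g_X, g_cat = g_cat, g_an = g_an,
                 g_an_excl = g_an_excl, g_bsyn = g_bsyn),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Black-box energy parameters (magnitudes, kJ/g)\n")
  cat("  g_X      :", format(x$g_X), "\n")
  cat("  g_cat    :", paste(names(x$g_cat), format(x$g_cat), sep = " = ",
                            collapse = ", "), "\n")
  cat("  g_an     :", format(x$g_an), "\n")
  if (x$g_bsyn > 0 || x$g_an_excl != x$g_an) {
    cat("  g_an_excl:", format(x$g_an_excl), "\n")
    cat("  g_bsyn   :", format(x$g_bsyn), "\n")
  }
  invisible(x)
}

#' Mutual-effect coefficients for two degradable nutrients
#'
#' Phenomenological linear coefficients coupling the availability of one
#' degradable nutrient to the energetic efficiency of the other's catabolism
#' (`m_cat_1`, `m_cat_2`) and to the anabolic reaction (`m_an_1`, `m_an_2`).
#' `f_cat1(N2) = 1 + m_cat_1 * N2`, `f_cat2(N1) = 1 + m_cat_2 * N1`,
#' `f_an(N1, N2) = 1 + m_an_1 * N1 + m_an_2 * N2`. All coefficients are per
#' microgram of the respective nutrient.
#'
#' @param m_cat_1,m_cat_2 Catabolic mutual-effect coefficients (per ug).
#' @param m_an_1,m_an_2 Anabolic mutual-effect coefficients (per ug).
#' @return An object of class `"two_degradable_effects"`.
#' @examples
#' two_degradable_effects(m_cat_1 = 0.1, m_cat_2 = 0.1)
#' @export
two_degradable_effects <- function(m_cat_1 = 0, m_cat_2 = 0,
                                   m_an_1 = 0, m_an_2 = 0) {
  v <- c(m_cat_1 = m_cat_1, m_cat_2 = m_cat_2, m_an_1 = m_an_1, m_an_2 = m_an_2)
  if (!all(is.finite(v))) stop_validity("mutual-effect coefficients must be finite")
  structure(as.list(v), class = "two_degradable_effects")
}

#' Mutual-effect coefficients for a degradable nutrient plus a precursor
#'
#' Coefficients of the linear mutual-effect functions in the
#' degradable-nutrient / biomass-precursor model: `f_cat = 1 + m_cat * M_utl`
#' (dimensionless), `f_an = 1 + m_an_N * N + m_an_M * M_utl`,
#' `f_bsyn = 1 + m_bsyn * N`, where `M_utl` is the precursor utilisation
#' fraction in \[0, 1\] and `N` the degradable nutrient amount in micrograms.
#'
#' The constraint `1 + m_cat * u > 0` for all `u` in \[0, 1\] (i.e.
#' `m_cat > -1`) keeps the catabolic supply positive on both saturation
#' branches.
#'
#' @param m_cat Catabolic coefficient of `M_utl` (dimensionless, > -1).
#' @param m_an_N Anabolic coefficient of the degradable-nutrient amount
#'   (per ug).
#' @param m_an_M Anabolic coefficient of `M_utl` (dimensionless).
#' @param m_bsyn Biosynthesis coefficient of the degradable-nutrient amount
#'   (per ug).
#' @return An object of class `"precursor_effects"`.
#' @examples
#' precursor_effects(m_cat = -0.8, m_bsyn = 0.05)
#' @export
precursor_effects <- function(m_cat = 0, m_an_N = 0, m_an_M = 0, m_bsyn = 0) {
  v <- c(m_cat = m_cat, m_an_N = m_an_N, m_an_M = m_an_M, m_bsyn = m_bsyn)
  if (!all(is.finite(v))) stop_validity("mutual-effect coefficients must be finite")
  if (m_cat <= -1)
    stop_validity("m_cat must be > -1 so that 1 + m_cat * M_utl stays positive")
  structure(as.list(v), class = "precursor_effects")
}

#' Precursor requirement specification
#'
#' The mass of a biomass precursor required per unit of biomass formed,
#' used to evaluate the utilisation fraction `M_utl`. For a methionine-like
#' amino acid in *E. coli* biomass this is on the order of a few percent by
#' dry weight; the default is 0.02 ug precursor per ug biomass.
#'
#' @param q_req Precursor mass required per unit biomass (ug/ug), > 0.
#' @return An object of class `"precursor_spec"`.
#' @export
precursor_spec <- function(q_req = 0.02) {
  stopifnot(is.numeric(q_req), length(q_req) == 1L)
  if (!is.finite(q_req) || q_req <= 0) stop_validity("q_req must be > 0")
  structure(list(q_req = q_req), class = "precursor_spec")
}

#' Read or write model parameters as a flat key-value config file
#'
#' Serialises an [energy_params()] object together with optional mutual-effect
#' coefficients and a precursor requirement to a flat YAML mapping (keys
#' `g_X`, `g_cat.<nutrient>`, `g_an`, `g_an_excl`, `g_bsyn`, `m_*`, `q_req`),
#' and reads such a file back.
#'
#' @param params An [energy_params()] object.
#' @param file Path to the YAML file.
#' @param effects Optional [two_degradable_effects()] or
#'   [precursor_effects()] object.
#' @param spec Optional [precursor_spec()] object.
#' @return `read_params()` returns a list with elements `params` and, when
#'   present in the file, `effects` and `spec`. `write_params()` returns
#'   `file` invisibly.
#' @export
write_params <- function(params, file, effects = NULL, spec = NULL) {
  stopifnot(inherits(params, "energy_params"))
  kv <- list(g_X = params$g_X, g_an = params$g_an,
             g_an_excl = params$g_an_excl, g_bsyn = params$g_bsyn)
  for (nm in names(params$g_cat))
    kv[[paste0("g_cat.", nm)]] <- unname(params$g_cat[[nm]])
  if (!is.null(effects)) {
    stopifnot(inherits(effects, c("two_degradable_effects", "precursor_effects")))
    kv$effects_model <- if (inherits(effects, "precursor_effects"))
      "precursor" else "two_degradable"
    kv <- c(kv, unclass(effects))
  }
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "precursor_spec"))
    kv$q_req <- spec$q_req
  }
  yaml::write_yaml(kv, file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  kv <- yaml::read_yaml(file)
  gi <- grep("^g_cat\\.", names(kv))
  if (!length(gi)) stop("no g_cat.<nutrient> entries found in ", file)
  g_cat <- vapply(kv[gi], as.numeric, 0)
  names(g_cat) <- sub("^g_cat\\.", "", names(kv)[gi])
  out <- list(params = energy_params(
    g_X = kv$g_X, g_cat = g_cat, g_an = kv$g_an,
    g_an_excl = if (is.null(kv$g_an_excl)) kv$g_an else kv$g_an_excl,
    g_bsyn = if (is.null(kv$g_bsyn)) 0 else kv$g_bsyn))
  if (!is.null(kv$effects_model)) {
    out$effects <- if (kv$effects_model == "precursor")
      precursor_effects(m_cat = kv$m_cat %||% 0, m_an_N = kv$m_an_N %||% 0,
                        m_an_M = kv$m_an_M %||% 0, m_bsyn = kv$m_bsyn %||% 0)
    else
      two_degradable_effects(m_cat_1 = kv$m_cat_1 %||% 0,
                             m_cat_2 = kv$m_cat_2 %||% 0,
                             m_an_1 = kv$m_an_1 %||% 0,
                             m_an_2 = kv$m_an_2 %||% 0)
  }
  if (!is.null(kv$q_req)) out$spec <- precursor_spec(kv$q_req)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# structured error for model-validity violations (never silently clipped)
stop_validity <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("multiyield_validity_error", "error"),
                      call = call))
}
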