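#' Average replicate endpoint measurements into an endpoint table
#'
#' Collapses per-well produced-biomass values to one row per condition
#' (base amount, measured amount): the replicate mean, its standard error
#' (`sd / sqrt(n)`, reported as 0 for single replicates) and the replicate
#' count. Rows are ordered by base amount, then measured amount, so the
#' result is invariant to input order. All downstream fits operate on these
#' replicate means.
#'
#' @param per_well Data frame with columns `measured_amount_ug`,
#'   `base_amount_ug`, `delta_B_ug`, and optionally `well` (checked for
#'   duplicates).
#' @return Data frame of class `"endpoint_table"` with columns
#'   `measured_amount_ug`, `base_amount_ug`, `delta_B_mean_ug`,
#'   `delta_B_se_ug`, `n_reps`.
#' @export
average_replicates <- function(per_well) {
  need <- c("measured_amount_ug", "base_amount_ug", "delta_B_ug")
  stopifnot(is.data.frame(per_well), all(need %in% names(per_well)))
  if ("well" %in% names(per_well) && anyDuplicated(per_well$well))
    stop("duplicate well ids in per-well table")
  key <- interaction(per_well$base_amount_ug, per_well$measured_amount_ug,
                     drop = TRUE)
  agg <- lapply(split(per_well, key), function(d) {
    n <- nrow(d)
    data.frame(measured_amount_ug = d$measured_amount_ug[1],
               base_amount_ug = d$base_amount_ug[1],
               delta_B_mean_ug = mean(d$delta_B_ug),
               delta_B_se_ug = if (n > 1) stats::sd(d$delta_B_ug) / sqrt(n) else 0,
               n_reps = n)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$base_amount_ug, out$measured_amount_ug), ]
  rownames(out) <- NULL
  structure(out, class = c("endpoint_table", "data.frame"))
}

# R^2 of an OLS line through (x, y); 1 when the fit is exact (including
# zero-variance y, which a horizontal line reproduces perfectly)
.window_r2 <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx < 1e-300) return(NA_real_)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  sst <- sum((y - mean(y))^2)
  sse <- sst - slope^2 * sxx
  if (sst < 1e-12 * max(1, mean(y)^2)) return(1)
  max(0, 1 - sse / sst)
}

# OLS line with hand-computed standard errors (no warning on perfect fits)
.ols_line <- function(x, y) {
  n <- length(x)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  if (sxx < 1e-300) stop("degenerate x-values in fit range")
  slope <- sum((x - xbar) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * xbar
  sse <- sum((y - intercept - slope * x)^2)
  sigma2 <- if (n > 2) sse / (n - 2) else 0
  list(slope = slope, intercept = intercept, sse = sse,
       slope_se = sqrt(sigma2 / sxx),
       intercept_se = sqrt(sigma2 * (1 / n + xbar^2 / sxx)),
       r2 = .window_r2(x, y), n = n)
}

#' Detect the linear region of an endpoint table
#'
#' Finds the longest contiguous run of points (at a single base amount) whose
#' ordinary least-squares fit of mean produced biomass against measured
#' amount reaches the R-squared threshold. Ties in length are broken by
#' higher R-squared, then by the leftmost run. All contiguous windows are
#' enumerated exhaustively.
#'
#' @param table An [average_replicates()] endpoint table restricted to one
#'   base amount.
#' @param r2_min Minimum R-squared for a qualifying run (default 0.9).
#' @param min_points Minimum run length (default 4).
#' @return Integer vector `c(first, last)` of row indices into `table`.
#' @export
detect_linear_region <- function(table, r2_min = 0.9, min_points = 4L) {
  stopifnot(is.data.frame(table), nrow(table) >= min_points)
  if (length(unique(table$base_amount_ug)) > 1L)
    stop("endpoint table spans several base amounts; subset to one before ",
         "detecting the linear region")
  x <- table$measured_amount_ug
  y <- table$delta_B_mean_ug
  n <- length(x)
  best <- NULL
  for (len in n:min_points) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      r2 <- .window_r2(x[i:j], y[i:j])
      if (!is.na(r2) && r2 >= r2_min) {
        if (is.null(best) || len > best$len ||
            (len == best$len && r2 > best$r2 + 1e-12))
          best <- list(i = i, j = j, len = len, r2 = r2)
      }
    }
    if (!is.null(best)) break  # longest qualifying length found
  }
  if (is.null(best))
    stop(errorCondition(
      sprintf(paste0("no contiguous run of >= %d points reaches R^2 >= %.3g; ",
                     "supply the fit range manually"), min_points, r2_min),
      class = c("multiyield_no_linear_region", "error")))
  c(best$i, best$j)
}

#' Overall biomass yield as the slope of a linear fit
#'
#' Ordinary least squares of mean produced biomass against the measured
#' nutrient amount over a row range; the slope is the overall biomass yield
#' of the measured nutrient and the intercept the contribution of the base
#' nutrient. Fits use the unweighted replicate means.
#'
#' @param table An endpoint table (one base amount).
#' @param range Row index range `c(first, last)`; defaults to
#'   [detect_linear_region()].
#' @param r2_min,min_points Passed to [detect_linear_region()] when `range`
#'   is `NULL`.
#' @return Object of class `"linear_fit"`: `slope` (the yield, ug biomass
#'   per ug nutrient), `intercept` (ug), `r2`, `slope_se`, `intercept_se`,
#'   `range`, `n`.
#' @export
fit_overall_yield <- function(table, range = NULL, r2_min = 0.9,
                              min_points = 4L) {
  stopifnot(is.data.frame(table))
  if (is.null(range)) range <- detect_linear_region(table, r2_min, min_points)
  stopifnot(length(range) == 2L, range[1] >= 1L, range[2] <= nrow(table),
            range[1] < range[2])
  idx <- range[1]:range[2]
  x <- table$measured_amount_ug[idx]
  y <- table$delta_B_mean_ug[idx]
  if (length(unique(x)) < 2L) stop("degenerate x-values in fit range")
  ols <- .ols_line(x, y)
  structure(list(slope = ols$slope, intercept = ols$intercept, r2 = ols$r2,
                 slope_se = ols$slope_se, intercept_se = ols$intercept_se,
                 range = as.integer(range), n = length(idx)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Overall biomass yield (slope): %.5g +/- %.3g ug/ug\n",
              x$slope, x$slope_se))
  cat(sprintf("  intercept %.5g ug, R^2 = %.4f, rows %d-%d (n = %d)\n",
              x$intercept, x$r2, x$range[1], x$range[2], x$n))
  invisible(x)
}

# F-test of an OLS line against a constant model on the same points
.slope_f_test <- function(x, y) {
  n <- length(x)
  fit <- stats::lm(y ~ x)
  sse1 <- sum(stats::residuals(fit)^2)
  sse0 <- sum((y - mean(y))^2)
  if (sse1 < 1e-300) return(list(F = Inf, p = 0))
  F <- (sse0 - sse1) / (sse1 / (n - 2))
  list(F = F, p = stats::pf(F, 1, n - 2, lower.tail = FALSE))
}

#' Two-phase segmented linear fit of an endpoint table
#'
#' Fits a continuous-x segmented model with one breakpoint: the breakpoint is
#' searched exhaustively over the observed measured amounts (points at or
#' below the breakpoint form segment 1), each segment receives its own
#' ordinary least-squares line, and the breakpoint minimising the total sum
#' of squared errors wins (ties go to the smaller breakpoint). Each segment
#' is additionally tested against a constant model with an F-test at
#' alpha = 0.05; segments whose slope is not significant are flagged as
#' consistent with a constant. When the two slopes agree within two combined
#' standard errors the fit is flagged effectively linear.
#'
#' @param table An endpoint table (one base amount) with at least 6 rows.
#' @param min_segment Minimum points per segment (default 3).
#' @return Object of class `"segmented_fit"`: `slope1`, `slope2`,
#'   `slope1_se`, `slope2_se`, `breakpoint_ug`, `r2_1`, `r2_2`, `sse`,
#'   `constant_phase_flags` (length 2), `p_slope` (length 2),
#'   `effectively_linear`, `break_index`.
#' @export
fit_segmented_two_phase <- function(table, min_segment = 3L) {
  stopifnot(is.data.frame(table), nrow(table) >= 6L, min_segment >= 3L)
  x <- table$measured_amount_ug
  y <- table$delta_B_mean_ug
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  cand <- unique(x)[seq_len(length(unique(x)))]
  cand <- cand[vapply(cand, function(bp)
    sum(x <= bp) >= min_segment && sum(x > bp) >= min_segment, TRUE)]
  if (!length(cand))
    stop("fewer than ", min_segment, " points available per candidate segment")
  seg_ols <- function(xi, yi) .ols_line(xi, yi)
  # ties in total SSE go to the larger breakpoint: on exactly piecewise data
  # the kink point lies on both lines, and the slope change is at the kink
  tol_tie <- 1e-9 * max(1, sum((y - mean(y))^2))
  best <- NULL
  for (bp in sort(cand)) {
    i1 <- x <= bp
    s1 <- seg_ols(x[i1], y[i1]); s2 <- seg_ols(x[!i1], y[!i1])
    sse <- s1$sse + s2$sse
    if (is.null(best) || sse < best$sse + tol_tie)
      best <- list(bp = bp, s1 = s1, s2 = s2,
                   sse = if (is.null(best)) sse else min(sse, best$sse))
  }
  i1 <- x <= best$bp
  t1 <- .slope_f_test(x[i1], y[i1]); t2 <- .slope_f_test(x[!i1], y[!i1])
  comb_se <- sqrt(best$s1$slope_se^2 + best$s2$slope_se^2) +
             1e-9 * max(abs(best$s1$slope), abs(best$s2$slope), 1)
  structure(list(slope1 = best$s1$slope, slope2 = best$s2$slope,
                 slope1_se = best$s1$slope_se, slope2_se = best$s2$slope_se,
                 breakpoint_ug = best$bp,
                 r2_1 = best$s1$r2, r2_2 = best$s2$r2, sse = best$sse,
                 constant_phase_flags = c(t1$p >= 0.05, t2$p >= 0.05),
                 p_slope = c(t1$p, t2$p),
                 effectively_linear =
                   abs(best$s1$slope - best$s2$slope) <= 2 * comb_se,
                 break_index = sum(i1)),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented fit: breakpoint at %.4g ug\n", x$breakpoint_ug))
  cat(sprintf("  phase 1 slope %.5g +/- %.3g (R^2 = %.3f)%s\n",
              x$slope1, x$slope1_se, x$r2_1,
              if (x$constant_phase_flags[1]) " [consistent with constant]" else ""))
  cat(sprintf("  phase 2 slope %.5g +/- %.3g (R^2 = %.3f)%s\n",
              x$slope2, x$slope2_se, x$r2_2,
              if (x$constant_phase_flags[2]) " [consistent with constant]" else ""))
  if (x$effectively_linear) cat("  slopes agree within 2 SE: effectively linear\n")
  invisible(x)
}

#' Overall biomass yield as a function of base-nutrient amount
#'
#' Assembles per-base-amount overall-yield estimates into a profile and fits
#' a line through them, quantifying how the yield of the measured nutrient
#' responds to the initial amount of the base nutrient. For the expanded
#' two-degradable model with anabolic coefficients zero the trend slope is
#' the reduced catabolic interaction `dm_CAT / (g_X + g_an)`.
#'
#' @param fits Named list of [fit_overall_yield()] objects, names giving the
#'   base amounts (ug), or a data frame with columns `base_amount_ug`,
#'   `yield`, `yield_se`.
#' @return Object of class `"yield_profile"`: `profile` (data frame
#'   `base_amount_ug`, `yield`, `yield_se`) and `trend` (a `"linear_fit"`-like
#'   list with `slope`, `intercept`, `slope_se`, `r2`).
#' @export
yield_vs_base_analysis <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("base_amount_ug", "yield") %in% names(fits)))
    prof <- fits
    if (is.null(prof$yield_se)) prof$yield_se <- NA_real_
  } else {
    stopifnot(is.list(fits), length(fits) >= 2L, !is.null(names(fits)))
    prof <- data.frame(base_amount_ug = as.numeric(names(fits)),
                       yield = vapply(fits, function(f) f$slope, 0),
                       yield_se = vapply(fits, function(f) f$slope_se, 0))
  }
  if (anyDuplicated(prof$base_amount_ug)) stop("base amounts must be unique")
  if (nrow(prof) < 2L) stop("need yields at >= 2 base amounts")
  prof <- prof[order(prof$base_amount_ug), ]
  rownames(prof) <- NULL
  ols <- .ols_line(prof$base_amount_ug, prof$yield)
  trend <- list(slope = ols$slope, intercept = ols$intercept,
                slope_se = ols$slope_se, r2 = ols$r2)
  structure(list(profile = prof, trend = trend), class = "yield_profile")
}

#' @export
print.yield_profile <- function(x, ...) {
  cat("Overall biomass yield vs base-nutrient amount:\n")
  print(x$profile, row.names = FALSE)
  cat(sprintf("Trend: slope %.5g +/- %.3g per ug (R^2 = %.4f)\n",
              x$trend$slope, x$trend$slope_se, x$trend$r2))
  invisible(x)
}

#' @export
plot.yield_profile <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$base_amount_ug, p$yield,
                 xlab = "base nutrient amount (ug)",
                 ylab = "overall biomass yield (ug/ug)", pch = 19, ...)
  if (any(is.finite(p$yield_se)))
    graphics::arrows(p$base_amount_ug, p$yield - p$yield_se,
                     p$base_amount_ug, p$yield + p$yield_se,
                     angle = 90, code = 3, length = 0.03)
  graphics::abline(x$trend$intercept, x$trend$slope, lty = 2)
  invisible(x)
}

#' Acetate secretion rate from supernatant measurements
#'
#' The slope of acetate concentration against OD600 across all replicates,
#' multiplied by the measured exponential growth rate, gives the acetate
#' secretion rate in mM per OD unit per hour. When a calibration model is
#' supplied the rate is additionally expressed per gram dry weight
#' (mmol gDCW^-1 h^-1) through the dry-weight conversion factor.
#'
#' @param points Data frame with columns `od600` and `acetate_mM` (>= 3
#'   rows, non-degenerate OD values).
#' @param mu Exponential growth rate, per hour, > 0.
#' @param cal Optional [calibration_model()] for the specific-rate
#'   conversion.
#' @return Object of class `"secretion_rate"`: `rate_mM_per_od_h`,
#'   `slope_mM_per_od`, `slope_se`, `mu_per_h`, and
#'   `rate_mmol_per_gdcw_h` when `cal` is given.
#' @export
acetate_secretion_rate <- function(points, mu, cal = NULL) {
  stopifnot(is.data.frame(points),
            all(c("od600", "acetate_mM") %in% names(points)),
            nrow(points) >= 3L, is.numeric(mu), length(mu) == 1L)
  if (!is.finite(mu) || mu <= 0) stop("mu must be a positive growth rate")
  if (length(unique(points$od600)) < 2L) stop("degenerate OD values")
  ols <- .ols_line(points$od600, points$acetate_mM)
  out <- list(rate_mM_per_od_h = ols$slope * mu, slope_mM_per_od = ols$slope,
              slope_se = ols$slope_se, mu_per_h = mu)
  if (!is.null(cal)) {
    stopifnot(inherits(cal, "calibration_model"))
    out$rate_mmol_per_gdcw_h <- ols$slope * mu / cal$dw_per_od_l
  }
  structure(out, class = "secretion_rate")
}

#' @export
print.secretion_rate <- function(x, ...) {
  cat(sprintf("Acetate secretion rate: %.4g mM OD^-1 h^-1 (slope %.4g mM/OD x mu %.3g /h)\n",
              x$rate_mM_per_od_h, x$slope_mM_per_od, x$mu_per_h))
  if (!is.null(x$rate_mmol_per_gdcw_h))
    cat(sprintf("  specific rate: %.4g mmol gDCW^-1 h^-1\n", x$rate_mmol_per_gdcw_h))
  invisible(x)
}
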