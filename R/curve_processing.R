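#' Optical-density calibration model
#'
#' Describes how raw plate-reader OD600 readings are turned into biomass dry
#' weight: an optional monotone piecewise-linear linearisation map (raw OD to
#' linearised OD; identity when no calibration curve is supplied), the
#' dry-weight conversion factor (default 0.396 g dry weight per litre per OD
#' unit) and the culture volume per well (default 200 ul).
#'
#' @param od_map Optional data frame with columns `raw_od` and `linear_od`
#'   giving a monotone non-decreasing calibration curve; `NULL` for identity.
#' @param dw_per_od_l Dry weight per OD per litre, g/(L OD), > 0.
#' @param well_volume_l Culture volume per well, litres, > 0.
#' @return An object of class `"calibration_model"`.
#' @examples
#' calibration_model()  # identity map, 0.396 g/(L OD), 200 ul
#' @export
calibration_model <- function(od_map = NULL, dw_per_od_l = 0.396,
                              well_volume_l = 2e-4) {
  stopifnot(is.numeric(dw_per_od_l), dw_per_od_l > 0,
            is.numeric(well_volume_l), well_volume_l > 0)
  if (!is.null(od_map)) {
    stopifnot(is.data.frame(od_map),
              all(c("raw_od", "linear_od") %in% names(od_map)),
              nrow(od_map) >= 2L)
    od_map <- od_map[order(od_map$raw_od), c("raw_od", "linear_od")]
    if (anyDuplicated(od_map$raw_od))
      stop("calibration raw_od values must be distinct")
    if (any(diff(od_map$linear_od) < 0))
      stop_validity("calibration map must be monotone non-decreasing")
  }
  structure(list(od_map = od_map, dw_per_od_l = dw_per_od_l,
                 well_volume_l = well_volume_l),
            class = "calibration_model")
}

# piecewise-linear linearisation with end-segment extrapolation (warns)
linearize_od <- function(cal, od) {
  if (is.null(cal$od_map)) return(od)
  x <- cal$od_map$raw_od
  y <- cal$od_map$linear_od
  out_of_range <- od < min(x) | od > max(x)
  if (any(out_of_range))
    warning(sum(out_of_range),
            " OD reading(s) outside calibration range; extrapolating",
            call. = FALSE)
  n <- length(x)
  lin <- stats::approx(x, y, xout = pmin(pmax(od, x[1]), x[n]))$y
  lo <- od < x[1]
  hi <- od > x[n]
  s1 <- (y[2] - y[1]) / (x[2] - x[1])
  sn <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  lin[lo] <- y[1] + s1 * (od[lo] - x[1])
  lin[hi] <- y[n] + sn * (od[hi] - x[n])
  lin
}

# invert a monotone calibration map (used by the plate generator)
delinearize_od <- function(cal, linear_od) {
  if (is.null(cal$od_map)) return(linear_od)
  x <- cal$od_map$linear_od
  y <- cal$od_map$raw_od
  if (any(diff(x) <= 0))
    stop("calibration map is not strictly increasing; cannot invert")
  n <- length(x)
  out <- stats::approx(x, y, xout = pmin(pmax(linear_od, x[1]), x[n]))$y
  lo <- linear_od < x[1]; hi <- linear_od > x[n]
  out[lo] <- y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (linear_od[lo] - x[1])
  out[hi] <- y[n] + (y[n] - y[n - 1]) / (x[n] - x[n - 1]) * (linear_od[hi] - x[n])
  out
}

#' Convert an OD600 time series to a biomass trajectory
#'
#' Linearises the raw OD readings through the calibration map and converts
#' them to micrograms of dry weight per well:
#' `biomass_ug = od_map(od) * dw_per_od_l * well_volume_l * 1e6`.
#' With the defaults (identity map, 0.396 g/(L OD), 200 ul) an OD of 1.0
#' corresponds to 79.2 ug.
#'
#' @param series Data frame with columns `time_h` (strictly increasing) and
#'   `od600` (>= 0).
#' @param cal A [calibration_model()].
#' @return Data frame of class `"biomass_trajectory"` with columns `time_h`
#'   and `biomass_ug`.
#' @export
od_to_biomass <- function(series, cal = calibration_model()) {
  stopifnot(is.data.frame(series), all(c("time_h", "od600") %in% names(series)),
            inherits(cal, "calibration_model"))
  t <- series$time_h; od <- series$od600
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("time_h must be finite and strictly increasing")
  if (any(!is.finite(od)) || any(od < 0))
    stop("od600 must be finite and >= 0")
  b <- linearize_od(cal, od) * cal$dw_per_od_l * cal$well_volume_l * 1e6
  structure(data.frame(time_h = t, biomass_ug = b),
            class = c("biomass_trajectory", "data.frame"))
}

#' Produced biomass from a growth curve
#'
#' The produced biomass of a batch culture: the biomass at a fixed window
#' after the curve maximum (default 4 h, the mid-range of a 3-5 h
#' stationary-phase window) minus the inoculum biomass at the first sample.
#' The sample nearest the target time is used; no interpolation is performed,
#' matching discrete plate-reader sampling.
#'
#' @param traj A [od_to_biomass()] trajectory (data frame with `time_h`,
#'   `biomass_ug`).
#' @param window_after_max_h Hours after the biomass maximum at which the
#'   final point is read.
#' @return Produced biomass `delta_B`, ug.
#' @export
produced_biomass_from_curve <- function(traj, window_after_max_h = 4) {
  stopifnot(is.data.frame(traj),
            all(c("time_h", "biomass_ug") %in% names(traj)),
            window_after_max_h >= 0)
  i_max <- which.max(traj$biomass_ug)
  target <- traj$time_h[i_max] + window_after_max_h
  if (max(traj$time_h) < target - 1e-9)
    stop(sprintf(paste0("trajectory ends %.2f h after its maximum but the ",
                        "endpoint window requires %.2f h; missing %.2f h of data"),
                 max(traj$time_h) - traj$time_h[i_max], window_after_max_h,
                 target - max(traj$time_h)))
  i_end <- which.min(abs(traj$time_h - target))
  traj$biomass_ug[i_end] - traj$biomass_ug[1L]
}

#' Exponential growth rate from a biomass trajectory
#'
#' Fits log-linear regressions in a sliding window along the trajectory and
#' returns the slope of the best-fitting window (highest R-squared; ties go
#' to the earliest window). A result whose best window does not reach
#' R-squared 0.95 is flagged unreliable.
#'
#' @param traj A biomass trajectory (data frame with `time_h`, `biomass_ug`).
#' @param window_points Number of samples per window (default 7, about 1 h at
#'   10-min sampling).
#' @return List of class `"growth_rate_fit"`: `mu_per_h`, `r2`, `t_start`,
#'   `t_end`, `window` (index range) and `reliable`.
#' @export
estimate_growth_rate <- function(traj, window_points = 7L) {
  stopifnot(is.data.frame(traj), window_points >= 3L)
  ok <- traj$biomass_ug > 0
  if (sum(ok) < window_points)
    stop("need at least ", window_points, " samples with positive biomass")
  t <- traj$time_h[ok]; y <- log(traj$biomass_ug[ok])
  n <- length(t)
  best <- list(r2 = -Inf, slope = NA_real_, i = NA_integer_)
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    tx <- t[idx]; yy <- y[idx]
    sxx <- sum((tx - mean(tx))^2)
    sxy <- sum((tx - mean(tx)) * (yy - mean(yy)))
    slope <- sxy / sxx
    sst <- sum((yy - mean(yy))^2)
    sse <- sst - slope * sxy
    r2 <- if (sst < 1e-300) 0 else max(0, 1 - sse / sst)
    if (r2 > best$r2 + 1e-12) best <- list(r2 = r2, slope = slope, i = i)
  }
  idx <- best$i:(best$i + window_points - 1L)
  structure(list(mu_per_h = best$slope, r2 = best$r2,
                 t_start = t[idx[1]], t_end = t[idx[length(idx)]],
                 window = c(idx[1], idx[length(idx)]),
                 reliable = best$r2 >= 0.95),
            class = "growth_rate_fit")
}

#' @export
print.growth_rate_fit <- function(x, ...) {
  cat(sprintf("Growth rate: %.4g /h (R^2 = %.4f, window %.2f-%.2f h)%s\n",
              x$mu_per_h, x$r2, x$t_start, x$t_end,
              if (x$reliable) "" else " [flagged unreliable]"))
  invisible(x)
}

#' Segment a diauxic growth curve into two phases and a plateau
#'
#' Detects up to two exponential growth phases separated by a plateau, the
#' classical diauxic pattern of growth on a preferred substrate followed,
#' after a lag, by growth on a secondary substrate (e.g. previously secreted
#' acetate). The log-biomass is smoothed with a centred 5-sample moving
#' average, its time derivative is computed, and an exhaustive two-changepoint
#' grid search minimises the within-segment variance of that derivative. The
#' curve is declared single-phase when the plateau's mean specific growth
#' rate is not clearly below the first phase's or no distinct second phase
#' follows.
#'
#' @param traj A biomass trajectory with at least 20 samples.
#' @param decimate_to Maximum number of candidate changepoint positions; the
#'   grid is thinned evenly above this (search stays deterministic).
#' @return List of class `"diauxic_segmentation"`: `diauxic` (logical),
#'   `phase1`, `plateau`, `phase2` (each with `t_start`, `t_end`, and for the
#'   growth phases `gain_ug` and `mu_per_h`; `phase2`/`plateau` are `NULL`
#'   for single-phase curves) and `lag2_h` (plateau duration).
#' @export
segment_diauxic_phases <- function(traj, decimate_to = 200L) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 20L)
  t <- traj$time_h
  b <- pmax(traj$biomass_ug, 1e-9 * max(traj$biomass_ug, 1))
  # drop the stationary tail: keep up to the first sample reaching 99.5% of
  # the (lightly smoothed) maximum, so the changepoints describe
  # phase 1 | lag | phase 2 rather than the final plateau
  nb <- length(b)
  bs <- vapply(seq_len(nb), function(i) {
    j <- max(1L, i - 2L):min(nb, i + 2L); mean(b[j])
  }, 0)
  i_stat <- which(bs >= 0.995 * max(bs))[1]
  if (!is.na(i_stat) && i_stat >= 20L) {
    traj <- traj[seq_len(i_stat), , drop = FALSE]
    t <- t[seq_len(i_stat)]
    b <- b[seq_len(i_stat)]
  }
  y <- log(b)
  # centred moving average over 5 samples (edges use shorter windows)
  n <- length(y)
  ys <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - 2L):min(n, i + 2L); mean(y[j])
  }, 0)
  # derivative by central differences
  dydt <- c((ys[2] - ys[1]) / (t[2] - t[1]),
            (ys[3:n] - ys[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
            (ys[n] - ys[n - 1]) / (t[n] - t[n - 1]))
  m <- length(dydt)
  cand <- 3:(m - 3)
  if (length(cand) > decimate_to)
    cand <- cand[unique(round(seq(1, length(cand), length.out = decimate_to)))]
  css <- function(v) sum((v - mean(v))^2)
  best <- list(sse = Inf, i = NA_integer_, j = NA_integer_)
  for (i in cand) {
    s1 <- css(dydt[1:i])
    for (j in cand[cand > i + 1L]) {
      sse <- s1 + css(dydt[(i + 1L):j]) + css(dydt[(j + 1L):m])
      if (sse < best$sse - 1e-15) best <- list(sse = sse, i = i, j = j)
    }
  }
  i <- best$i; j <- best$j
  seg_mu <- function(a, z) {
    idx <- a:z
    stats::coef(stats::lm(y[idx] ~ t[idx]))[[2]]
  }
  r1 <- mean(dydt[1:i]); rp <- mean(dydt[(i + 1L):j]); r2 <- mean(dydt[(j + 1L):m])
  diauxic <- is.finite(r1) && r1 > 0 && rp < 0.3 * r1 && r2 > 3 * abs(rp) + 0.02
  phase1_end <- if (diauxic) i else n
  phase1 <- list(t_start = t[1], t_end = t[phase1_end],
                 gain_ug = traj$biomass_ug[phase1_end] - traj$biomass_ug[1],
                 mu_per_h = seg_mu(1L, phase1_end))
  if (!diauxic)
    return(structure(list(diauxic = FALSE, phase1 = phase1, plateau = NULL,
                          phase2 = NULL, lag2_h = NA_real_),
                     class = "diauxic_segmentation"))
  plateau <- list(t_start = t[i], t_end = t[j])
  phase2 <- list(t_start = t[j], t_end = t[n],
                 gain_ug = traj$biomass_ug[n] - traj$biomass_ug[j],
                 mu_per_h = seg_mu(j, n))
  structure(list(diauxic = TRUE, phase1 = phase1, plateau = plateau,
                 phase2 = phase2, lag2_h = t[j] - t[i]),
            class = "diauxic_segmentation")
}

#' @export
print.diauxic_segmentation <- function(x, ...) {
  if (!x$diauxic) {
    cat(sprintf("Single growth phase: gain %.4g ug, mu = %.3g /h\n",
                x$phase1$gain_ug, x$phase1$mu_per_h))
    return(invisible(x))
  }
  cat(sprintf("Diauxic growth curve:\n  phase 1: %.2f-%.2f h, gain %.4g ug, mu = %.3g /h\n",
              x$phase1$t_start, x$phase1$t_end, x$phase1$gain_ug, x$phase1$mu_per_h))
  cat(sprintf("  plateau: %.2f-%.2f h (lag %.2f h)\n",
              x$plateau$t_start, x$plateau$t_end, x$lag2_h))
  cat(sprintf("  phase 2: %.2f-%.2f h, gain %.4g ug, mu = %.3g /h\n",
              x$phase2$t_start, x$phase2$t_end, x$phase2$gain_ug, x$phase2$mu_per_h))
  invisible(x)
}

#' Read plate-reader inputs from CSV
#'
#' `read_timeseries()` reads a long-format time-series file with columns
#' `well`, `time_h`, `od600`; `read_layout()` reads a plate-layout table with
#' columns `well`, `measured_nutrient`, `measured_amount_ug`,
#' `base_nutrient`, `base_amount_ug`, `replicate`; `read_calibration()` reads
#' a two-column calibration curve (`raw_od`, `linear_od`) and returns a
#' [calibration_model()].
#'
#' @param file Path to the CSV file.
#' @param ... Passed on to [calibration_model()] (conversion factor, volume).
#' @return A data frame, or a [calibration_model()] for
#'   `read_calibration()`.
#' @export
read_timeseries <- function(file) {
  ts <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("well", "time_h", "od600")
  if (!all(need %in% names(ts)))
    stop("time-series CSV must have columns: ", paste(need, collapse = ", "))
  ts
}

#' @rdname read_timeseries
#' @export
read_layout <- function(file) {
  lay <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("well", "measured_nutrient", "measured_amount_ug",
            "base_nutrient", "base_amount_ug", "replicate")
  if (!all(need %in% names(lay)))
    stop("layout CSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(lay$well)) stop("duplicate well ids in layout")
  lay
}

#' @rdname read_timeseries
#' @export
read_calibration <- function(file, ...) {
  calibration_model(od_map = utils::read.csv(file, stringsAsFactors = FALSE), ...)
}

#' Extract per-well endpoint produced biomass from a plate
#'
#' Runs the curve-processing chain for every well of a plate: OD
#' linearisation and dry-weight conversion, then endpoint produced biomass a
#' fixed window after the curve maximum. The result is the per-well input of
#' [average_replicates()].
#'
#' @param timeseries Long-format data frame (`well`, `time_h`, `od600`).
#' @param layout Plate-layout data frame (see [read_layout()]).
#' @param cal A [calibration_model()].
#' @param window_after_max_h Endpoint window, hours after the maximum.
#' @return Data frame with one row per well: `well`, `measured_amount_ug`,
#'   `base_amount_ug`, `replicate`, `delta_B_ug`.
#' @export
extract_endpoints <- function(timeseries, layout, cal = calibration_model(),
                              window_after_max_h = 4) {
  stopifnot(is.data.frame(timeseries), is.data.frame(layout))
  wells <- unique(timeseries$well)
  missing_layout <- setdiff(wells, layout$well)
  if (length(missing_layout))
    stop("wells absent from layout: ", paste(missing_layout, collapse = ", "))
  rows <- lapply(wells, function(w) {
    ts <- timeseries[timeseries$well == w, c("time_h", "od600")]
    ts <- ts[order(ts$time_h), ]
    traj <- od_to_biomass(ts, cal)
    lr <- layout[layout$well == w, , drop = FALSE]
    data.frame(well = w,
               measured_amount_ug = lr$measured_amount_ug,
               base_amount_ug = lr$base_amount_ug,
               replicate = lr$replicate,
               delta_B_ug = produced_biomass_from_curve(traj, window_after_max_h))
  })
  do.call(rbind, rows)
}
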