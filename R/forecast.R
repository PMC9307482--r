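#' Forecasting configuration
#'
#' Assumptions used by the clinical forecasting helpers: the symmetric
#' division rate, the wild-type pool size, the sequencing depth of a
#' follow-up assay and the width of the prediction band in standard
#' deviations.
#'
#' @param lambda Symmetric division rate per year (default 1).
#' @param n_w Wild-type stem-cell pool size (default 1e5).
#' @param depth Assumed follow-up sequencing depth (default 2000).
#' @param sd_multiplier Band half-width in standard deviations (default 2).
#' @return A `cf_forecast_config` list.
#' @export
forecast_config <- function(lambda = 1, n_w = 1e5, depth = 2000,
                            sd_multiplier = 2) {
  if (lambda <= 0 || n_w <= 0 || depth <= 0 || sd_multiplier <= 0) {
    abort("All forecast parameters must be positive.")
  }
  structure(list(lambda = lambda, n_w = n_w, depth = depth,
                 sd_multiplier = sd_multiplier),
            class = "cf_forecast_config")
}

# Moments of the predicted VAF after dt years for a clone observed at VAF v0:
# invert the VAF map for the initial size, evolve mean/variance under the
# birth-death transition, map back with the delta method.
forecast_moments <- function(v0, s, dt, config) {
  n0 <- clone_size_from_vaf(v0, config$n_w)
  mom <- transition_moments(n0, s, config$lambda, dt)
  m <- mom$mean
  v_mean <- m / (2 * (config$n_w + m))
  dv_dn <- config$n_w / (2 * (config$n_w + m)^2)
  list(n0 = n0, mean_n = m, var_n = mom$variance,
       v_mean = v_mean, dv_dn = dv_dn,
       var_process = mom$variance * dv_dn^2,
       var_sampling = v_mean * (1 - v_mean) / config$depth)
}

#' Predicted VAF band after a follow-up interval
#'
#' Given a clone at initial VAF `v0` with fitness `s`, predicts the VAF
#' distribution `dt` years later: the initial clone size is obtained by
#' inverting the VAF map, the birth-death transition supplies the mean and
#' process variance, binomial sampling variance at the configured depth is
#' added, and the band is `mean +/- sd_multiplier * SD`, truncated to
#' `[0, 0.5)`.
#'
#' @param v0 Initial VAF in (0, 0.5).
#' @param s Fitness per year.
#' @param dt Follow-up interval in years (vectorised, >= 0).
#' @param config A [forecast_config()].
#' @return A tibble: `dt`, `mean`, `sd`, `lower`, `upper`.
#' @export
predict_vaf_band <- function(v0, s, dt, config = forecast_config()) {
  if (v0 <= 0 || v0 >= 0.5) abort("`v0` must lie strictly in (0, 0.5).")
  if (any(dt < 0)) abort("`dt` must be non-negative.")
  fm <- forecast_moments(v0, s, dt, config)
  sd_v <- sqrt(fm$var_process + fm$var_sampling)
  k <- config$sd_multiplier
  tibble::tibble(dt = dt, mean = fm$v_mean, sd = sd_v,
                 lower = pmax(0, fm$v_mean - k * sd_v),
                 upper = pmin(0.5 - 1e-12, fm$v_mean + k * sd_v))
}

#' Minimum referral time for confident growth measurement
#'
#' The smallest follow-up interval after which a clone's growth exceeds its
#' own uncertainty. Two detection criteria are available:
#'
#' * `"growth"` (default): the expected VAF growth minus
#'   `sd_multiplier` standard deviations of that growth must be positive,
#'   where the growth SD combines the birth-death process variance with the
#'   binomial uncertainty of the initial clone size (measured once at the
#'   configured depth) propagated through the expected expansion. The
#'   follow-up assay's own sampling noise is not part of this criterion; it
#'   is reported separately by [predict_vaf_band()].
#' * `"band"`: the lower edge of [predict_vaf_band()] (which includes
#'   follow-up sampling noise) must clear the initial VAF's upper sampling
#'   band `v0 + sd_multiplier * sqrt(v0 (1 - v0) / depth)`. This is far more
#'   conservative: at typical depths the sampling noise exceeds months of
#'   growth, so referral times stretch to years.
#'
#' @inheritParams predict_vaf_band
#' @param criterion Detection criterion, see above.
#' @param max_years Give up beyond this horizon (default 50).
#' @param resolution Bisection resolution in years (default 0.01).
#' @return Referral time in years, or `NA` when `s <= 0` or the horizon is
#'   exceeded.
#' @export
referral_time <- function(v0, s, config = forecast_config(),
                          criterion = c("growth", "band"),
                          max_years = 50, resolution = 0.01) {
  if (v0 <= 0 || v0 >= 0.5) abort("`v0` must lie strictly in (0, 0.5).")
  criterion <- match.arg(criterion)
  if (s <= 0) return(NA_real_)
  k <- config$sd_multiplier

  sd_v0 <- sqrt(v0 * (1 - v0) / config$depth)
  # initial clone-size uncertainty from one measurement at the assay depth
  sd_n0 <- sd_v0 * 2 * config$n_w / (1 - 2 * v0)^2

  f <- function(dt) {
    fm <- forecast_moments(v0, s, dt, config)
    if (criterion == "growth") {
      growth_var <- fm$var_process +
        (expm1(s * dt) * sd_n0 * fm$dv_dn)^2
      (fm$v_mean - v0) - k * sqrt(growth_var)
    } else {
      (fm$v_mean - k * sqrt(fm$var_process + fm$var_sampling)) -
        (v0 + k * sd_v0)
    }
  }
  if (f(max_years) <= 0) return(NA_real_)
  lo <- 0
  hi <- max_years
  while (hi - lo > resolution / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  round(hi / resolution) * resolution
}

#' Minimum fitness detectable within a follow-up interval
#'
#' The smallest fitness on a fine grid whose [referral_time()] does not
#' exceed `dt`, so that `referral_time(v0, min_detectable_fitness(v0, dt))
#' <= dt` up to grid resolution.
#'
#' @inheritParams referral_time
#' @param dt Available follow-up interval in years (> 0).
#' @param s_grid Fitness values searched (default 0.001 to 1 by 0.001).
#' @return Fitness per year, or `NA` if no grid value suffices.
#' @export
min_detectable_fitness <- function(v0, dt, config = forecast_config(),
                                   criterion = c("growth", "band"),
                                   s_grid = seq(0.001, 1, by = 0.001)) {
  if (dt <= 0) abort("`dt` must be positive.")
  criterion <- match.arg(criterion)
  rt <- function(s) referral_time(v0, s, config, criterion)
  ok <- function(s) {
    r <- rt(s)
    !is.na(r) && r <= dt
  }
  if (!ok(s_grid[length(s_grid)])) return(NA_real_)
  # referral time is non-increasing in s: binary search the grid
  lo <- 1L
  hi <- length(s_grid)
  if (ok(s_grid[lo])) return(s_grid[lo])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ok(s_grid[mid])) hi <- mid else lo <- mid
  }
  s_grid[hi]
}

#' Referral-time and minimum-fitness grids
#'
#' Convenience sweeps producing tidy grids of [referral_time()] over
#' (initial VAF, fitness) and of [min_detectable_fitness()] over
#' (initial VAF, interval), suitable for contour-style summaries.
#'
#' @param v0 Initial VAFs.
#' @param s Fitness values per year.
#' @param dt Follow-up intervals in years.
#' @param config A [forecast_config()].
#' @return A tibble: `v0`, `s`, `referral_years` (or `v0`, `dt`, `s_min`).
#' @export
referral_grid <- function(v0 = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1),
                          s = seq(0.05, 0.5, by = 0.05),
                          config = forecast_config()) {
  grid <- tidyr::expand_grid(v0 = v0, s = s)
  grid$referral_years <- purrr::map2_dbl(grid$v0, grid$s, function(v, ss) {
    referral_time(v, ss, config)
  })
  grid
}

#' @rdname referral_grid
#' @export
min_fitness_grid <- function(v0 = c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1),
                             dt = c(0.5, 1, 2, 3, 5, 10),
                             config = forecast_config()) {
  grid <- tidyr::expand_grid(v0 = v0, dt = dt)
  grid$s_min <- purrr::map2_dbl(grid$v0, grid$dt, function(v, d) {
    min_detectable_fitness(v, d, config)
  })
  grid
}
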