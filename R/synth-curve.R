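#' Configuration for a synthetic calibration curve
#'
#' The synthetic curve is a linear cal-BP to 14C-age trend plus a smooth
#' sum of random-phase sinusoids ("wiggles"), constrained to remain
#' strictly monotone so that the mapping is invertible and a true calendar
#' age can be recovered by calibration.
#'
#' @param cal_range length-2 calendar interval (cal BP) covered by the curve.
#' @param step grid step (yr).
#' @param slope 14C yr per cal yr of the linear trend.
#' @param wiggle_amp amplitude of each sinusoidal component (14C yr);
#'   0 gives an exactly linear curve.
#' @param wiggle_period base period of the wiggles (yr).
#' @param n_wiggles number of sinusoidal components.
#' @param curve_sd per-point curve 1-sigma (14C yr).
#' @param seed integer seed.
#' @return a list of class `curve_sim_config`.
#' @export
curve_sim_config <- function(cal_range = c(8000, 20000), step = 5,
                             slope = 0.95, wiggle_amp = 40,
                             wiggle_period = 900, n_wiggles = 3,
                             curve_sd = 15, seed = 1) {
  stopifnot(length(cal_range) == 2L, cal_range[1] < cal_range[2])
  .check_range(step, "step", 0, lo_open = TRUE)
  .check_range(slope, "slope", 0, lo_open = TRUE)
  .check_range(wiggle_amp, "wiggle_amp", 0)
  .check_range(wiggle_period, "wiggle_period", 0, lo_open = TRUE)
  .check_range(curve_sd, "curve_sd", 0)
  structure(list(cal_range = cal_range, step = step, slope = slope,
                 wiggle_amp = wiggle_amp, wiggle_period = wiggle_period,
                 n_wiggles = n_wiggles, curve_sd = curve_sd,
                 seed = as.integer(seed)),
            class = "curve_sim_config")
}

#' Generate a synthetic, strictly monotone calibration curve
#'
#' Wiggle amplitude is damped (by factors of 0.8) until the sampled curve is
#' strictly increasing in 14C age with calendar age, which guarantees an
#' invertible ground-truth mapping. The inverse lookup (true cal age for a
#' given 14C age) is returned for round-trip testing.
#'
#' @param cfg a [curve_sim_config].
#' @return a [cal_curve] with attributes `truth` (list with the generating
#'   parameters, the damped amplitude actually used, and `inverse`, a
#'   function mapping 14C age to true cal BP).
#' @export
gen_calibration_curve <- function(cfg = curve_sim_config()) {
  stopifnot(inherits(cfg, "curve_sim_config"))
  set.seed(cfg$seed)
  grid <- seq(cfg$cal_range[1], cfg$cal_range[2], by = cfg$step)
  phases <- stats::runif(cfg$n_wiggles, 0, 2 * pi)
  periods <- cfg$wiggle_period * (1 + 0.7 * seq_len(cfg$n_wiggles))
  amp <- cfg$wiggle_amp
  repeat {
    w <- rep(0, length(grid))
    for (j in seq_len(cfg$n_wiggles))
      w <- w + amp * sin(2 * pi * grid / periods[j] + phases[j])
    mu <- cfg$slope * grid + w
    if (all(diff(mu) > 0) || amp == 0) break
    amp <- amp * 0.8
    if (amp < 1e-6) { amp <- 0 }
  }
  curve <- cal_curve(grid, mu, cfg$curve_sd, name = "synthetic")
  inv <- stats::approxfun(mu, grid)
  attr(curve, "truth") <- list(cfg = cfg, amp_used = amp, inverse = inv)
  curve
}
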