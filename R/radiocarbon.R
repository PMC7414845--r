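#' Radiocarbon calibration and replicate combination
#'
#' Tools to combine replicate radiocarbon determinations by inverse-variance
#' weighting, to calibrate conventional radiocarbon ages against a calibration
#' curve, and to report highest posterior density (HPD) ranges.
#'
#' A calibration curve is a table mapping calendar age (cal BP, i.e. calendar
#' years before 1950) to the conventional radiocarbon age a sample of that
#' calendar age would measure, together with the curve's own 1-sigma
#' uncertainty. Calibration inverts this mapping probabilistically: the
#' posterior density over calendar age t is proportional to
#' \deqn{\exp\left(-\frac{(y - \mu(t))^2}{2(\sigma^2 + s(t)^2)}\right)}
#' for a determination y +/- sigma, curve mean mu(t) and curve error s(t),
#' under a uniform prior on t.
#'
#' @name radiocarbon
NULL

#' Construct a calibration curve object
#'
#' @param cal_bp numeric vector of calendar ages (cal BP), strictly monotone.
#' @param c14_age radiocarbon age of the curve at each `cal_bp` (14C yr BP).
#' @param error 1-sigma curve uncertainty (14C yr); recycled if scalar.
#' @param name curve label.
#' @return an object of class `cal_curve`: a data frame with columns
#'   `cal_bp`, `c14_age`, `error`, sorted by increasing `cal_bp`.
#' @export
cal_curve <- function(cal_bp, c14_age, error, name = "custom") {
  if (length(cal_bp) < 2L) .pc_stop("a calibration curve needs >= 2 points")
  if (length(c14_age) != length(cal_bp))
    .pc_stop("`cal_bp` and `c14_age` lengths differ")
  error <- rep_len(error, length(cal_bp))
  if (any(error < 0)) .pc_stop("curve `error` must be >= 0")
  d <- diff(cal_bp)
  if (!(all(d > 0) || all(d < 0)))
    .pc_stop("`cal_bp` grid must be strictly monotone")
  o <- order(cal_bp)
  out <- data.frame(cal_bp = cal_bp[o], c14_age = c14_age[o],
                    error = error[o])
  attr(out, "name") <- name
  class(out) <- c("cal_curve", "data.frame")
  out
}

#' Read a calibration curve in IntCal format
#'
#' IntCal curve files (e.g. `intcal13.14c`) are comma-separated tables with
#' header lines starting with `#` and columns CAL BP, 14C age BP, and the
#' curve 1-sigma error (further columns, Delta14C, are ignored).
#'
#' @param path path to a `.14c` file.
#' @param name curve label; defaults to the file name.
#' @return a [cal_curve] object.
#' @export
read_intcal <- function(path, name = basename(path)) {
  if (!file.exists(path)) .pc_stop("calibration curve file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  f <- utils::read.csv(text = lines, header = FALSE)
  if (ncol(f) < 3L) .pc_stop("IntCal file must have >= 3 comma-separated columns")
  cal_curve(f[[1]], f[[2]], f[[3]], name = name)
}

#' A radiocarbon determination
#'
#' @param age conventional radiocarbon age (14C yr BP).
#' @param sigma 1-sigma measurement uncertainty (yr), > 0.
#' @param lab_code optional laboratory code.
#' @return object of class `c14_measurement`.
#' @export
c14_measurement <- function(age, sigma, lab_code = NA_character_) {
  .check_range(sigma, "sigma", lo = 0, lo_open = TRUE)
  structure(list(age = age, sigma = sigma, lab_code = lab_code),
            class = "c14_measurement")
}

#' @export
print.c14_measurement <- function(x, ...) {
  cat(sprintf("14C age: %.0f +/- %.0f BP", x$age, x$sigma),
      if (!is.na(x$lab_code)) sprintf(" [%s]", x$lab_code) else "", "\n",
      sep = "")
  invisible(x)
}

#' Combine replicate radiocarbon measurements
#'
#' Inverse-variance weighted mean of replicate determinations of the same
#' sample, with combined sigma `(sum w_i)^{-1/2}`, `w_i = 1/sigma_i^2`.
#' Replicate consistency is checked with a chi-square test on the weighted
#' residuals (df = n - 1); an inconsistent set still returns the combination
#' but carries a warning.
#'
#' @param measurements a list of [c14_measurement] objects (or a single one).
#' @param alpha significance level for the consistency warning.
#' @return a [c14_measurement] with attributes `chisq`, `df`, `p_value`,
#'   `consistent`.
#' @export
combine_measurements <- function(measurements, alpha = 0.05) {
  if (inherits(measurements, "c14_measurement"))
    measurements <- list(measurements)
  if (length(measurements) < 1L) .pc_stop("need at least one measurement")
  ages <- vapply(measurements, `[[`, numeric(1), "age")
  sig <- vapply(measurements, `[[`, numeric(1), "sigma")
  w <- 1 / sig^2
  mean_age <- sum(w * ages) / sum(w)
  comb_sigma <- 1 / sqrt(sum(w))
  if (length(ages) > 1L) {
    chisq <- sum(w * (ages - mean_age)^2)
    df <- length(ages) - 1L
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- 0; df <- 0L; p <- NA_real_
  }
  consistent <- is.na(p) || p >= alpha
  if (!consistent)
    .pc_warn("replicate measurements inconsistent (chi-square = %.2f, df = %d, p = %.3g)",
             chisq, df, p)
  out <- c14_measurement(mean_age, comb_sigma,
                         lab_code = paste(stats::na.omit(vapply(
                           measurements, `[[`, character(1), "lab_code")),
                           collapse = "+"))
  attr(out, "chisq") <- chisq
  attr(out, "df") <- df
  attr(out, "p_value") <- p
  attr(out, "consistent") <- consistent
  out
}

# interpolate a curve to a 1-yr grid (linear in mu and s)
.curve_grid <- function(curve, step = 1) {
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = step)
  mu <- stats::approx(curve$cal_bp, curve$c14_age, xout = grid)$y
  s <- stats::approx(curve$cal_bp, curve$error, xout = grid)$y
  list(cal_bp = grid, mu = mu, s = s)
}

#' Calibrate a radiocarbon determination
#'
#' Computes the posterior density over calendar age on a 1 cal-yr grid
#' (curve interpolated linearly in both mean and error) and reports
#' highest-posterior-density ranges at the requested mass: the smallest
#' density-ranked set of grid ages reaching the mass, merged into
#' contiguous ranges. Endpoints are not rounded.
#'
#' @param m a [c14_measurement], or a numeric age (then `sigma` is required).
#' @param curve a [cal_curve].
#' @param mass probability mass for the HPD ranges (default 0.954).
#' @param sigma 1-sigma error when `m` is numeric.
#' @param step grid step in calendar years.
#' @return object of class `cal_date`: list with `cal_bp` (grid), `density`
#'   (sums to 1 over the grid), `hpd` (data frame older/younger/mass),
#'   `mode` (grid age of maximum density), `measurement`, `mass`.
#' @export
calibrate_c14 <- function(m, curve, mass = 0.954, sigma = NULL, step = 1) {
  if (is.numeric(m)) {
    if (is.null(sigma)) .pc_stop("numeric `m` requires `sigma`")
    m <- c14_measurement(m, sigma)
  }
  stopifnot(inherits(curve, "cal_curve"))
  .check_range(mass, "mass", 0, 1, lo_open = TRUE, hi_open = TRUE)
  rng <- range(curve$c14_age)
  if (m$age < rng[1] - 10 * m$sigma || m$age > rng[2] + 10 * m$sigma)
    .pc_stop("age %.0f BP outside the 14C range of curve '%s' (%.0f..%.0f)",
             m$age, attr(curve, "name"), rng[1], rng[2])
  g <- .curve_grid(curve, step = step)
  dens <- stats::dnorm(m$age, mean = g$mu, sd = sqrt(m$sigma^2 + g$s^2))
  tot <- sum(dens)
  if (tot <= 0) .pc_stop("posterior mass is zero on the curve support")
  dens <- dens / tot
  hpd <- .hpd_ranges(g$cal_bp, dens, mass)
  structure(list(cal_bp = g$cal_bp, density = dens, hpd = hpd,
                 mode = g$cal_bp[which.max(dens)],
                 measurement = m, mass = mass),
            class = "cal_date")
}

# density-ranked HPD ranges over a regular grid; each grid point stands
# for a cell of one grid step, so ranges extend half a step past the
# outermost selected points (otherwise true ages falling in the boundary
# half-cells are missed and the HPD undercovers)
.hpd_ranges <- function(grid, dens, mass) {
  o <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[o])
  k <- which(cum >= mass)[1]
  if (is.na(k)) k <- length(dens)
  sel <- sort(o[seq_len(k)])
  step <- if (length(grid) > 1L) grid[2] - grid[1] else 1
  brk <- c(0L, which(diff(sel) > 1L), length(sel))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- sel[(brk[i] + 1L):brk[i + 1L]]
    data.frame(older = max(grid[idx]) + step / 2,
               younger = min(grid[idx]) - step / 2,
               mass = sum(dens[idx]))
  }))
  out[order(-out$older), , drop = FALSE]
}

#' @export
print.cal_date <- function(x, ...) {
  cat(sprintf("Calibrated date for %.0f +/- %.0f BP (mode %.0f cal BP)\n",
              x$measurement$age, x$measurement$sigma, x$mode))
  cat(sprintf("%.1f%% HPD ranges (cal BP):\n", 100 * x$mass))
  for (i in seq_len(nrow(x$hpd)))
    cat(sprintf("  %.0f - %.0f  (%.1f%%)\n", x$hpd$older[i],
                x$hpd$younger[i], 100 * x$hpd$mass[i]))
  invisible(x)
}
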