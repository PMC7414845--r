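#' Synthetic crown-outline populations
#'
#' Outlines are built from a truncated Fourier series on the polar radius
#' around a fixed base shape (an elongated crown with two cusp bumps),
#' which guarantees closed, star-shaped (hence non-self-intersecting)
#' curves with directly controllable group contrast: group differences,
#' within-group noise and allometric displacement all act on the Fourier
#' coefficients. Two anchor landmarks sit at polar angles 0 and pi.
#'
#' @name synth_outlines
NULL

#' Configuration for the outline population generator
#'
#' @param n_per_group specimens per group (defaults 21 and 23, the dog and
#'   wolf sample sizes of the crown-outline analysis).
#' @param group_labels labels of the two groups.
#' @param n_fourier number of Fourier harmonics carrying variation.
#' @param group_offset length `2 * n_fourier` contrast vector on the
#'   coefficients (+offset/2 to group 2, -offset/2 to group 1); see
#'   [outline_contrast()] for a calibrated helper. NULL = no contrast.
#' @param within_sd per-coefficient within-group standard deviation.
#' @param allometry_slope length `2 * n_fourier` coefficient displacement
#'   per unit log centroid size (NULL = isometry); see
#'   [allometry_slope_for_r2()].
#' @param size_range min/max centroid size (uniform draw).
#' @param n_points points per generated outline polygon.
#' @param seed integer seed.
#' @return list of class `outline_pop_config`.
#' @export
outline_pop_config <- function(n_per_group = c(21, 23),
                               group_labels = c("dog", "wolf"),
                               n_fourier = 8, group_offset = NULL,
                               within_sd = 0.004,
                               allometry_slope = NULL,
                               size_range = c(9, 13), n_points = 180,
                               seed = 1) {
  stopifnot(length(n_per_group) == 2L, length(group_labels) == 2L,
            length(size_range) == 2L)
  if (any(n_per_group < 2)) .pc_stop("each group needs n >= 2")
  .check_range(within_sd, "within_sd", 0)
  if (size_range[1] >= size_range[2])
    .pc_stop("size_range must satisfy min < max")
  nf <- as.integer(n_fourier)
  if (is.null(group_offset)) group_offset <- rep(0, 2 * nf)
  if (length(group_offset) != 2 * nf)
    .pc_stop("group_offset must have length 2 * n_fourier = %d", 2 * nf)
  if (is.null(allometry_slope)) allometry_slope <- rep(0, 2 * nf)
  if (length(allometry_slope) != 2 * nf)
    .pc_stop("allometry_slope must have length 2 * n_fourier = %d", 2 * nf)
  if (n_points %% 2L != 0L) .pc_stop("n_points must be even")
  structure(list(n_per_group = n_per_group, group_labels = group_labels,
                 n_fourier = nf, group_offset = group_offset,
                 within_sd = within_sd, allometry_slope = allometry_slope,
                 size_range = size_range, n_points = as.integer(n_points),
                 seed = as.integer(seed)),
            class = "outline_pop_config")
}

# fixed base radius: elongated crown with two cusp bumps
.base_radius <- function(theta) {
  cd <- function(t, c) { d <- abs(t - c) %% (2 * pi); pmin(d, 2 * pi - d) }
  1 + 0.18 * cos(2 * theta) +
    0.15 * exp(-(cd(theta, 1.0) / 0.45)^2) +
    0.20 * exp(-(cd(theta, 2.2) / 0.50)^2)
}

# radius perturbation from a coefficient vector (a_1..a_f, b_1..b_f)
.fourier_radius <- function(theta, coef) {
  nf <- length(coef) / 2
  r <- 0
  for (j in seq_len(nf))
    r <- r + coef[j] * cos(j * theta) + coef[nf + j] * sin(j * theta)
  r
}

# build the outline polygon for one coefficient vector and size
.make_outline <- function(coef, cs, n_points) {
  theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
  r <- .base_radius(theta) + .fourier_radius(theta, coef)
  if (min(r) < 0.1) return(NULL)  # would self-intersect / degenerate
  p <- cbind(r * cos(theta), r * sin(theta))
  p <- sweep(p, 2, colMeans(p))
  p * (cs / centroid_size(p))
}

#' Calibrated group-contrast vector
#'
#' Builds a coefficient offset whose norm is `rel` times the expected norm
#' of a within-group deviation vector (`within_sd * sqrt(2 n_fourier)`), so
#' that `rel = 3` produces a between-group mean separation about three
#' times the typical within-group deviation. The direction is a fixed mix
#' of low harmonics unless supplied.
#'
#' @param n_fourier harmonic count of the target configuration.
#' @param within_sd within-group per-coefficient sd of the target config.
#' @param rel contrast ratio (offset norm / expected deviation norm).
#' @param direction optional unit direction (length `2 * n_fourier`).
#' @return numeric contrast vector of length `2 * n_fourier`.
#' @export
outline_contrast <- function(n_fourier, within_sd, rel = 3,
                             direction = NULL) {
  if (is.null(direction)) {
    direction <- rep(0, 2 * n_fourier)
    direction[2] <- 0.8                       # cos 2theta
    direction[n_fourier + 3] <- 0.6           # sin 3theta
  }
  direction <- direction / sqrt(sum(direction^2))
  rel * within_sd * sqrt(2 * n_fourier) * direction
}

#' Allometric slope targeting a given R-squared on the contrast axis
#'
#' With allometry acting along the group-contrast direction, the score on
#' the leading between-group axis decomposes into the group term (half the
#' offset norm, h), isotropic within-group noise (sd w) and the allometric
#' component s * (log cs - mean); its regression on log centroid size then
#' has population R^2 = s^2 V / (s^2 V + h^2 + w^2) with V the variance of
#' log size. This solves for s and returns the slope vector along the
#' contrast direction.
#'
#' @param target_r2 desired population R-squared on the leading axis.
#' @param group_offset the contrast vector in use.
#' @param within_sd within-group per-coefficient sd.
#' @param size_range the generator's min/max centroid size.
#' @return slope vector (length of `group_offset`).
#' @export
allometry_slope_for_r2 <- function(target_r2, group_offset, within_sd,
                                   size_range) {
  .check_range(target_r2, "target_r2", 0, 1, lo_open = TRUE, hi_open = TRUE)
  nrm <- sqrt(sum(group_offset^2))
  if (nrm == 0) .pc_stop("group_offset must be non-zero")
  v <- group_offset / nrm
  h <- nrm / 2
  u <- seq(size_range[1], size_range[2], length.out = 20001)
  V <- stats::var(log(u))
  s <- sqrt(target_r2 / (1 - target_r2) * (h^2 + within_sd^2) / V)
  s * v
}

#' Generate a two-group outline population
#'
#' @param cfg an [outline_pop_config].
#' @param max_retry redraws allowed per specimen when a perturbation would
#'   produce a degenerate (non-star-shaped) outline.
#' @return list of class `outline_population`: `outlines` (list of
#'   [outline2d]), `groups`, and `truth` (config, per-specimen coefficient
#'   matrix, centroid sizes, the contrast vector and the mean log size).
#' @export
gen_outline_population <- function(cfg = outline_pop_config(),
                                   max_retry = 20) {
  stopifnot(inherits(cfg, "outline_pop_config"))
  set.seed(cfg$seed)
  nf2 <- 2 * cfg$n_fourier
  mlog <- mean(log(cfg$size_range))
  outlines <- list()
  groups <- character(0)
  coefs <- NULL
  sizes <- numeric(0)
  for (g in 1:2) {
    sign_g <- c(-1, 1)[g]
    for (i in seq_len(cfg$n_per_group[g])) {
      cs <- stats::runif(1, cfg$size_range[1], cfg$size_range[2])
      p <- NULL
      for (try in seq_len(max_retry)) {
        coef <- sign_g * cfg$group_offset / 2 +
          stats::rnorm(nf2, 0, cfg$within_sd) +
          cfg$allometry_slope * (log(cs) - mlog)
        p <- .make_outline(coef, cs, cfg$n_points)
        if (!is.null(p)) break
      }
      if (is.null(p))
        .pc_stop("could not generate a non-degenerate outline after %d tries",
                 max_retry)
      id <- sprintf("%s_%02d", cfg$group_labels[g], i)
      outlines[[length(outlines) + 1L]] <-
        outline2d(p, c(1L, cfg$n_points / 2L + 1L), specimen_id = id,
                  group = cfg$group_labels[g])
      groups <- c(groups, cfg$group_labels[g])
      coefs <- rbind(coefs, coef)
      sizes <- c(sizes, cs)
    }
  }
  structure(list(outlines = outlines, groups = groups,
                 truth = list(cfg = cfg, coefficients = coefs,
                              csize = sizes,
                              contrast = cfg$group_offset, mean_log_size = mlog)),
            class = "outline_population")
}

#' Noise-free group mean outline
#'
#' The outline a group member would have with zero within-group noise and
#' isometric size at the generator's central size: used to recover the
#' true contrast direction in shape space.
#'
#' @param cfg an [outline_pop_config].
#' @param group 1 or 2.
#' @return an [outline2d].
#' @export
gen_group_mean_outline <- function(cfg, group = 1) {
  stopifnot(inherits(cfg, "outline_pop_config"), group %in% 1:2)
  coef <- c(-1, 1)[group] * cfg$group_offset / 2
  p <- .make_outline(coef, exp(mean(log(cfg$size_range))), cfg$n_points)
  if (is.null(p)) .pc_stop("degenerate mean outline for this configuration")
  outline2d(p, c(1L, cfg$n_points / 2L + 1L),
            specimen_id = sprintf("mean_%s", cfg$group_labels[group]),
            group = cfg$group_labels[group])
}
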