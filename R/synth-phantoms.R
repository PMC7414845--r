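#' Configuration for the lower-carnassial tooth phantom
#'
#' The phantom emulates a two-cusped lower first molar: a crown whose
#' occlusal surface is the maximum of two Gaussian cusps (paraconid and
#' protoconid) and of two lateral crests connecting them, over an elliptic
#' footprint that tapers to the cervix line, with a dentine root below the
#' cervix plane and an enamel cap of controlled thickness above it. The
#' crests make the occlusal valley (fossa) between the cusps a closed
#' basin, so that the fossa floor lies below the level at which the enamel
#' cap splits into two cusp caps - the geometry the crown-slice protocol
#' relies on. Optional planar occlusal wear and a mesial cervix break can
#' be applied.
#'
#' @param grid_shape voxel grid dimensions (x = mesiodistal, y =
#'   buccolingual, z = crown axis).
#' @param voxel_mm isotropic voxel size (mm).
#' @param cusp_height_mm heights of the two cusps above the cervix (mm);
#'   must be distinct positions and positive heights.
#' @param cusp_offset_mm signed x offsets of the two cusp apices from the
#'   footprint centre (mm).
#' @param cusp_sigma_mm Gaussian radii of the two cusps (mm).
#' @param crest_height_frac crest height as a fraction of the lower cusp.
#' @param crest_offset_mm |y| position of the two crest ridges (mm).
#' @param crest_sigma_mm Gaussian radius of the crest ridges (mm).
#' @param footprint_mm ellipse semi-axes (x, y) of the crown footprint (mm).
#' @param z_cervix_mm height of the cervix plane above the grid origin (mm).
#' @param root_depth_mm dentine root depth below the cervix (mm).
#' @param enamel_thickness_mm enamel cap thickness (mm); must be smaller
#'   than the lower cusp height.
#' @param wear_truncation_frac fraction of the taller cusp's height removed
#'   by a planar occlusal truncation (0 = unworn).
#' @param cervix_break_frac fraction of the cervix's mesial x-extent
#'   removed (0 = intact).
#' @param intensity_means,intensity_sds per-tissue grayscale parameters
#'   (background, dentine, enamel).
#' @param seed integer seed (grayscale noise).
#' @return list of class `tooth_phantom_config`.
#' @export
tooth_phantom_config <- function(grid_shape = c(60, 44, 64), voxel_mm = 0.1,
                                 cusp_height_mm = c(2.6, 3.2),
                                 cusp_offset_mm = c(-1.2, 1.2),
                                 cusp_sigma_mm = c(0.7, 0.8),
                                 crest_height_frac = 0.62,
                                 crest_offset_mm = 0.95,
                                 crest_sigma_mm = 0.45,
                                 footprint_mm = c(2.6, 1.7),
                                 z_cervix_mm = 2.2, root_depth_mm = 1.4,
                                 enamel_thickness_mm = 0.3,
                                 wear_truncation_frac = 0,
                                 cervix_break_frac = 0,
                                 intensity_means = c(20, 110, 200),
                                 intensity_sds = c(5, 8, 8),
                                 seed = 1) {
  stopifnot(length(grid_shape) == 3L, length(cusp_height_mm) == 2L,
            length(cusp_offset_mm) == 2L, length(cusp_sigma_mm) == 2L,
            length(footprint_mm) == 2L, length(intensity_means) == 3L,
            length(intensity_sds) == 3L)
  if (cusp_offset_mm[1] == cusp_offset_mm[2])
    .pc_stop("the two cusp apices must be distinct")
  if (any(cusp_height_mm <= 0)) .pc_stop("cusp heights must be > 0")
  .check_range(enamel_thickness_mm, "enamel_thickness_mm", 0, lo_open = TRUE)
  if (enamel_thickness_mm >= min(cusp_height_mm))
    .pc_stop("enamel thicker than the lower cusp (%.2f >= %.2f mm)",
             enamel_thickness_mm, min(cusp_height_mm))
  .check_range(wear_truncation_frac, "wear_truncation_frac", 0, 1,
               hi_open = TRUE)
  .check_range(cervix_break_frac, "cervix_break_frac", 0, 1, hi_open = TRUE)
  structure(as.list(environment()), class = "tooth_phantom_config")
}

# occlusal surface height (above cervix, mm) at xy offsets from centre
.tooth_surface <- function(dx, dy, cfg) {
  rho2 <- (dx / cfg$footprint_mm[1])^2 + (dy / cfg$footprint_mm[2])^2
  edge <- pmax(0, 1 - rho2^2)
  h <- pmax(
    cfg$cusp_height_mm[1] *
      exp(-((dx - cfg$cusp_offset_mm[1])^2 + dy^2) /
            (2 * cfg$cusp_sigma_mm[1]^2)),
    cfg$cusp_height_mm[2] *
      exp(-((dx - cfg$cusp_offset_mm[2])^2 + dy^2) /
            (2 * cfg$cusp_sigma_mm[2]^2)))
  xr <- range(cfg$cusp_offset_mm)
  ramp <- exp(-pmax(0, pmax(xr[1] - dx, dx - xr[2]))^2 /
                (2 * cfg$crest_sigma_mm^2))
  crest <- cfg$crest_height_frac * min(cfg$cusp_height_mm) * ramp *
    exp(-(abs(dy) - cfg$crest_offset_mm)^2 / (2 * cfg$crest_sigma_mm^2))
  ifelse(rho2 <= 1, pmax(h, crest) * edge, 0)
}

#' Generate a tooth phantom
#'
#' @param cfg a [tooth_phantom_config].
#' @return list with `gray` (a [gray_volume]), `labels` (the ground-truth
#'   [label_volume]) and `truth`: cervix plane and height, the true fossa
#'   floor (`h1_mm`) and enamel-cap split level (`h2_mm`, both absolute z),
#'   apex coordinates, per-tissue voxel counts of the true crown slice and
#'   the true slice dentine percentage.
#' @export
gen_tooth_phantom <- function(cfg = tooth_phantom_config()) {
  stopifnot(inherits(cfg, "tooth_phantom_config"))
  set.seed(cfg$seed)
  d <- cfg$grid_shape
  vx <- cfg$voxel_mm
  cx <- d[1] * vx / 2; cy <- d[2] * vx / 2
  xs <- (seq_len(d[1]) - 0.5) * vx - cx
  ys <- (seq_len(d[2]) - 0.5) * vx - cy
  zs <- (seq_len(d[3]) - 0.5) * vx
  dx <- array(rep(xs, times = d[2] * d[3]), d)
  dy <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  zz <- array(rep(zs, each = d[1] * d[2]), d)
  surf <- array(.tooth_surface(as.vector(dx), as.vector(dy), cfg), d)
  rho2 <- (dx / cfg$footprint_mm[1])^2 + (dy / cfg$footprint_mm[2])^2
  crown <- rho2 <= 1 & zz > cfg$z_cervix_mm & zz <= cfg$z_cervix_mm + surf
  root <- rho2 <= 0.92 & zz <= cfg$z_cervix_mm &
    zz > cfg$z_cervix_mm - cfg$root_depth_mm
  tooth <- crown | root
  r_en <- max(1L, as.integer(round(cfg$enamel_thickness_mm / vx)))
  core <- .erode_ball(tooth, r_en)
  lab <- array(0L, d)
  lab[tooth] <- 1L                      # dentine
  lab[crown & !core] <- 2L              # enamel cap
  # planar occlusal wear
  if (cfg$wear_truncation_frac > 0) {
    z_wear <- cfg$z_cervix_mm +
      (1 - cfg$wear_truncation_frac) * max(cfg$cusp_height_mm)
    lab[zz > z_wear] <- 0L
  }
  # mesial cervix break
  if (cfg$cervix_break_frac > 0) {
    x_cut <- cfg$footprint_mm[1] * (1 - 2 * cfg$cervix_break_frac)
    lab[dx > x_cut & zz <= cfg$z_cervix_mm + 0.35] <- 0L
  }
  labels <- label_volume(lab, vx, tooth_semantics())
  # grayscale with per-tissue noise
  mu <- cfg$intensity_means[lab + 1L]
  sg <- cfg$intensity_sds[lab + 1L]
  gray <- gray_volume(array(mu + stats::rnorm(length(lab)) * sg, d), vx)

  # ground truth: apices, fossa floor along the inter-apex line, split level
  apex <- cbind(cx + cfg$cusp_offset_mm, cy,
                cfg$z_cervix_mm + .tooth_surface(cfg$cusp_offset_mm,
                                                 c(0, 0), cfg))
  tline <- seq(cfg$cusp_offset_mm[1], cfg$cusp_offset_mm[2],
               length.out = 1000)
  h1 <- cfg$z_cervix_mm + min(.tooth_surface(tline, rep(0, 1000), cfg))
  h2 <- cfg$z_cervix_mm + .split_level(cfg)
  slice <- zz > h1 & zz < h2
  n_dent <- sum(lab == 1L & slice)
  n_enam <- sum(lab == 2L & slice)
  truth <- list(cfg = cfg,
                cervix_plane = plane(c(0, 0, 1), cfg$z_cervix_mm),
                z_cervix_mm = cfg$z_cervix_mm,
                h1_mm = h1, h2_mm = h2, apex_mm = apex,
                slice_dentine_voxels = n_dent,
                slice_enamel_voxels = n_enam,
                slice_dentine_percent = 100 * n_dent / (n_dent + n_enam))
  list(gray = gray, labels = labels, truth = truth)
}

# level (above cervix) at which the occlusal surface's super-level set
# separates the two apices: bisection with 2D connectivity on a fine grid
.split_level <- function(cfg, res = 4L) {
  nx <- cfg$grid_shape[1] * res; ny <- cfg$grid_shape[2] * res
  vx <- cfg$voxel_mm / res
  xs <- (seq_len(nx) - 0.5) * vx - cfg$grid_shape[1] * cfg$voxel_mm / 2
  ys <- (seq_len(ny) - 0.5) * vx - cfg$grid_shape[2] * cfg$voxel_mm / 2
  gx <- matrix(rep(xs, ny), nx); gy <- matrix(rep(ys, each = nx), nx)
  s <- matrix(.tooth_surface(as.vector(gx), as.vector(gy), cfg), nx)
  ia <- vapply(cfg$cusp_offset_mm, function(x0)
    which.min(abs(xs - x0)), integer(1))
  iy0 <- which.min(abs(ys))
  split_at <- function(L) {
    m <- s > L
    if (!m[ia[1], iy0] || !m[ia[2], iy0]) return(TRUE)
    labm <- cc_label_3d(as.vector(m), c(nx, ny, 1L))
    labm[(iy0 - 1L) * nx + ia[1]] != labm[(iy0 - 1L) * nx + ia[2]]
  }
  lo <- 0; hi <- min(cfg$cusp_height_mm)
  if (split_at(lo)) return(lo)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (split_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Configuration for the metacarpal epiphysis phantom
#'
#' An ellipsoidal epiphysis of bone in which a fraction `porosity` of the
#' trabecular-compartment voxels are void. By default the whole epiphysis
#' is treated as trabecular (uniformly porous tissue, as in skeletally
#' immature bone where both trabecular and cortical tissue are porous); a
#' solid cortical shell of given thickness can be requested instead.
#'
#' @param grid_shape voxel grid dimensions.
#' @param voxel_mm isotropic voxel size (mm).
#' @param semi_axes_mm ellipsoid semi-axes (mm).
#' @param cortical_thickness_mm solid shell thickness (mm); 0 disables it.
#' @param porosity void fraction of the trabecular compartment, in [0, 1).
#' @param seed integer seed.
#' @return list of class `epiphysis_phantom_config`.
#' @export
epiphysis_phantom_config <- function(grid_shape = c(68, 68, 62),
                                     voxel_mm = 0.1,
                                     semi_axes_mm = c(2.95, 2.95, 2.65),
                                     cortical_thickness_mm = 0,
                                     porosity = 0.2, seed = 1) {
  stopifnot(length(grid_shape) == 3L, length(semi_axes_mm) == 3L)
  .check_range(porosity, "porosity", 0, 1, hi_open = TRUE)
  .check_range(cortical_thickness_mm, "cortical_thickness_mm", 0)
  structure(as.list(environment()), class = "epiphysis_phantom_config")
}

#' Generate an epiphysis phantom
#'
#' @param cfg an [epiphysis_phantom_config].
#' @return a [label_volume] with [bone_semantics()], with attribute `truth`:
#'   the realized trabecular void fraction, the trabecular voxel count, and
#'   a separation plane below the whole phantom (so the entire epiphysis is
#'   proximal to it).
#' @export
gen_epiphysis_phantom <- function(cfg = epiphysis_phantom_config()) {
  stopifnot(inherits(cfg, "epiphysis_phantom_config"))
  set.seed(cfg$seed)
  d <- cfg$grid_shape; vx <- cfg$voxel_mm
  ctr <- d * vx / 2
  xs <- (seq_len(d[1]) - 0.5) * vx - ctr[1]
  ys <- (seq_len(d[2]) - 0.5) * vx - ctr[2]
  zs <- (seq_len(d[3]) - 0.5) * vx - ctr[3]
  dx <- array(rep(xs, times = d[2] * d[3]), d)
  dy <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  dz <- array(rep(zs, each = d[1] * d[2]), d)
  r2 <- (dx / cfg$semi_axes_mm[1])^2 + (dy / cfg$semi_axes_mm[2])^2 +
    (dz / cfg$semi_axes_mm[3])^2
  bone <- r2 <= 1
  if (cfg$cortical_thickness_mm > 0) {
    sa <- pmax(cfg$semi_axes_mm - cfg$cortical_thickness_mm, 1e-6)
    trab <- (dx / sa[1])^2 + (dy / sa[2])^2 + (dz / sa[3])^2 <= 1
  } else {
    trab <- bone
  }
  lab <- array(0L, d)
  lab[bone] <- 1L
  idx <- which(trab)
  void <- idx[stats::runif(length(idx)) < cfg$porosity]
  lab[void] <- 0L
  out <- label_volume(lab, vx, bone_semantics())
  zmin <- min(dz[bone]) + ctr[3]
  attr(out, "truth") <- list(
    cfg = cfg,
    trabecular_voxels = length(idx),
    void_fraction = length(void) / length(idx),
    separation_plane = plane(c(0, 0, 1), zmin - vx))
  out
}
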