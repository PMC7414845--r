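#' Voxel volumes and planes
#'
#' Containers for 3D voxel data with isotropic voxel size: `gray_volume`
#' for reconstructed grayscale microCT data and `label_volume` for
#' segmented tissue labels, plus oriented planes used as tooth
#' cross-sections and epiphysis separators.
#'
#' @name volumes
NULL

#' Tissue label semantics
#'
#' Standard label maps: `tooth_semantics()` is
#' background 0 / dentine 1 / enamel 2; `bone_semantics()` is
#' background-or-void 0 / bone 1.
#' @return named integer vector mapping tissue name to label.
#' @export
tooth_semantics <- function() c(background = 0L, dentine = 1L, enamel = 2L)

#' @rdname tooth_semantics
#' @export
bone_semantics <- function() c(background = 0L, bone = 1L)

#' Construct a grayscale volume
#'
#' @param data 3D numeric array.
#' @param voxel_mm isotropic voxel edge length (mm).
#' @return object of class `gray_volume`.
#' @export
gray_volume <- function(data, voxel_mm) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  .check_range(voxel_mm, "voxel_mm", 0, lo_open = TRUE)
  structure(list(data = data, voxel_mm = voxel_mm), class = "gray_volume")
}

#' Construct a label volume
#'
#' @param data 3D integer array of tissue labels.
#' @param voxel_mm isotropic voxel edge length (mm).
#' @param semantics named integer vector mapping tissue names to labels,
#'   e.g. [tooth_semantics()].
#' @return object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_mm, semantics = tooth_semantics()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  .check_range(voxel_mm, "voxel_mm", 0, lo_open = TRUE)
  bad <- setdiff(unique(as.vector(data)), unname(semantics))
  if (length(bad))
    .pc_stop("labels not covered by the declared semantics: %s",
             paste(bad, collapse = ", "))
  structure(list(data = data, voxel_mm = voxel_mm, semantics = semantics),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume %dx%dx%d @ %.3g mm/voxel\n", d[1], d[2], d[3],
              x$voxel_mm))
  tab <- table(factor(as.vector(x$data), levels = unname(x$semantics),
                      labels = names(x$semantics)))
  print(tab)
  invisible(x)
}

# voxel-center coordinates (mm) of voxels selected by a logical mask or index
.voxel_coords <- function(vol, idx) {
  d <- dim(vol$data)
  if (is.logical(idx)) idx <- which(idx)
  a <- arrayInd(idx, d)
  (a - 0.5) * vol$voxel_mm
}

# logical mask of a named tissue
.tissue_mask <- function(vol, tissue) {
  lab <- vol$semantics[[tissue]]
  if (is.null(lab)) .pc_stop("tissue '%s' not in semantics", tissue)
  vol$data == lab
}

#' An oriented plane
#'
#' The plane is `{x : n . x = offset}` with unit normal `n`; the positive
#' side (`n . x > offset`) is the occlusal (tooth) or proximal (bone) side.
#'
#' @param normal length-3 vector (normalized internally).
#' @param offset signed offset (mm).
#' @return object of class `pc_plane`.
#' @export
plane <- function(normal, offset) {
  stopifnot(length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) .pc_stop("plane normal must be non-zero")
  # offset is interpreted against the unit normal, in mm
  structure(list(normal = normal / nn, offset = offset),
            class = "pc_plane")
}

#' @export
print.pc_plane <- function(x, ...) {
  cat(sprintf("plane: normal (%.3f, %.3f, %.3f), offset %.3f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

# signed heights of points (n x 3, mm) above a plane
.plane_height <- function(points, pl) {
  drop(points %*% pl$normal) - pl$offset
}

# orthonormal in-plane basis (u, v) for a plane
.plane_basis <- function(pl) {
  n <- pl$normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u = u, v = v)
}

#' Total-least-squares plane fit
#'
#' Fits a plane to a 3D point set by minimizing the sum of squared
#' orthogonal distances (centroid + smallest principal direction). Used to
#' fit the reference cross-section orientation to the cervix point set.
#'
#' @param points n x 3 matrix of coordinates (mm); n >= 3, non-collinear.
#' @param toward optional point (length 3); the normal is oriented so this
#'   point lies on the positive (occlusal) side.
#' @return a [plane], with attribute `rms` (orthogonal RMS residual).
#' @export
fit_cervix_plane <- function(points, toward = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) .pc_stop("plane fit needs >= 3 points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  s <- svd(x, nu = 0)
  if (s$d[2] < 1e-9 * max(s$d[1], 1e-300))
    .pc_stop("points are collinear; plane is undefined")
  n <- s$v[, 3]
  if (!is.null(toward) && sum((toward - ctr) * n) < 0) n <- -n
  pl <- plane(n, sum(n * ctr))
  attr(pl, "rms") <- sqrt(mean(.plane_height(points, pl)^2))
  pl
}

## ---- binary morphology on 3D masks (vectorized shifts) ----

# shift a 3D logical array by one voxel along an axis, padding FALSE
.shift1 <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1L)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1L); idx_src[[axis]] <- 2:d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# one 6-neighbourhood erosion / dilation step
.erode1 <- function(m) {
  out <- m
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out & .shift1(m, ax, dir)
  out
}

.dilate1 <- function(m) {
  out <- m
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out | .shift1(m, ax, dir)
  out
}

.erode <- function(m, k) { for (i in seq_len(k)) m <- .erode1(m); m }
.dilate <- function(m, k) { for (i in seq_len(k)) m <- .dilate1(m); m }

# shift by an arbitrary integer offset, padding FALSE
.shift_by <- function(m, off) {
  d <- dim(m)
  if (any(abs(off) >= d)) return(array(FALSE, d))
  dst <- src <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      dst[[ax]] <- (1L + o):d[ax]; src[[ax]] <- 1L:(d[ax] - o)
    } else {
      dst[[ax]] <- 1L:(d[ax] + o); src[[ax]] <- (1L - o):d[ax]
    }
  }
  out <- array(FALSE, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# integer offsets of a Euclidean ball of radius r voxels
.ball_offsets <- function(r) {
  s <- -floor(r):floor(r)
  g <- expand.grid(dx = s, dy = s, dz = s)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

# Euclidean-ball erosion / dilation / closing (isotropic, unlike iterated
# 6-neighbourhood steps, which carve deeper along diagonals)
.erode_ball <- function(m, r) {
  off <- .ball_offsets(r)
  out <- m
  for (i in seq_len(nrow(off))) {
    o <- as.integer(off[i, ])
    if (all(o == 0)) next
    out <- out & .shift_by(m, o)
  }
  out
}

.dilate_ball <- function(m, r) {
  off <- .ball_offsets(r)
  out <- m
  for (i in seq_len(nrow(off))) {
    o <- as.integer(off[i, ])
    if (all(o == 0)) next
    out <- out | .shift_by(m, o)
  }
  out
}

# closing with padding so the dilation is never clipped at the grid edge
.close_mask <- function(m, r) {
  d <- dim(m)
  p <- as.integer(ceiling(r))
  big <- array(FALSE, d + 2L * p)
  big[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- m
  big <- .erode_ball(.dilate_ball(big, r), r)
  big[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

## ---- 26-connectivity components (compiled) ----

# labels as an integer array; 0 = background
.components <- function(mask) {
  lab <- cc_label_3d(as.vector(mask), as.integer(dim(mask)))
  array(lab, dim(mask))
}

#' Rotate a volume by a multiple of 90 degrees about a grid axis
#'
#' Used to check that voxel-based measurements are invariant to axis
#' relabelling. Returns the rotated volume; a plane defined in the old
#' frame can be carried along with [rotate_plane()].
#'
#' @param vol a `label_volume` or `gray_volume`.
#' @param axis 1, 2 or 3: the grid axis to rotate about.
#' @param k number of quarter turns (counter-clockwise looking down +axis).
#' @return a volume of the same class.
#' @export
rotate_volume <- function(vol, axis = 3L, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  a <- vol$data
  other <- setdiff(1:3, axis)
  for (i in seq_len(k)) {
    perm <- 1:3
    perm[other] <- rev(other)
    a <- aperm(a, perm)
    # reverse the first of the two permuted axes
    idx <- lapply(dim(a), seq_len)
    idx[[other[1]]] <- rev(idx[[other[1]]])
    a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  out <- vol
  out$data <- a
  out
}

#' @rdname rotate_volume
#' @param pl a [plane] defined in the un-rotated volume's coordinates.
#' @param dim_mm grid extents (mm) of the un-rotated volume
#'   (`dim(data) * voxel_mm`).
#' @export
rotate_plane <- function(pl, axis = 3L, k = 1L, dim_mm) {
  k <- ((k %% 4) + 4) %% 4
  n <- pl$normal; d <- pl$offset; ext <- dim_mm
  other <- setdiff(1:3, axis)
  for (i in seq_len(k)) {
    # x' coordinates: x'[other1] = ext[other2] - x[other2]; x'[other2] = x[other1]
    n2 <- n; n2[other[1]] <- -n[other[2]]; n2[other[2]] <- n[other[1]]
    d2 <- d + n2[other[1]] * ext[other[2]]
    ext2 <- ext; ext2[other[1]] <- ext[other[2]]; ext2[other[2]] <- ext[other[1]]
    n <- n2; d <- d2; ext <- ext2
  }
  plane(n, d)
}
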