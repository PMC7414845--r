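#' Generalized Procrustes analysis (2D)
#'
#' Full Procrustes superimposition of a sample of 2D landmark
#' configurations: translations are removed by centering, every
#' configuration is scaled to unit centroid size (sizes are kept
#' separately), and rotations are chosen to minimize the summed squared
#' distance to the iteratively re-estimated mean shape. 2D rotations are
#' computed in closed form in the complex-number representation.
#'
#' @param configs list of k x 2 matrices (equal k), e.g. from
#'   [resample_outline()].
#' @param tol convergence threshold on the change of the mean shape.
#' @param max_iter iteration cap.
#' @return object of class `shape_set`: list with `coords` (k x 2 x n array
#'   of aligned shapes, centroid at origin, unit centroid size), `mean`
#'   (k x 2 consensus), `csize` (pre-scaling centroid sizes), `groups`,
#'   `specimen_ids`, `k`, `n`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 2L) .pc_stop("GPA needs >= 2 configurations")
  k <- nrow(configs[[1]])
  if (any(vapply(configs, nrow, integer(1)) != k))
    .pc_stop("configurations differ in landmark count")
  ids <- vapply(seq_along(configs), function(i) {
    s <- attr(configs[[i]], "specimen_id")
    if (is.null(s)) sprintf("spec_%d", i) else s
  }, character(1))
  grp <- vapply(configs, function(x) {
    g <- attr(x, "group"); if (is.null(g)) "unknown" else g
  }, character(1))
  z <- vapply(configs, function(x) {
    zz <- complex(real = x[, 1], imaginary = x[, 2])
    zz - mean(zz)
  }, complex(k))
  cs <- sqrt(colSums(Mod(z)^2))
  if (any(cs < 1e-12))
    .pc_stop("degenerate configuration: all landmarks coincident")
  z <- sweep(z, 2, cs, `/`)
  m <- z[, 1]
  m <- m / sqrt(sum(Mod(m)^2))
  for (it in seq_len(max_iter)) {
    # optimal rotation of each column onto the mean
    w <- drop(crossprod(Conj(z), m))       # sum(conj(z_i) * m)
    rot <- w / Mod(w)
    z <- sweep(z, 2, rot, `*`)
    m_new <- rowMeans(z)
    m_new <- m_new - mean(m_new)
    m_new <- m_new / sqrt(sum(Mod(m_new)^2))
    if (max(Mod(m_new - m)) < tol) { m <- m_new; break }
    m <- m_new
  }
  coords <- array(0, c(k, 2, length(configs)))
  coords[, 1, ] <- Re(z)
  coords[, 2, ] <- Im(z)
  structure(list(coords = coords, mean = cbind(Re(m), Im(m)), csize = cs,
                 groups = grp, specimen_ids = ids, k = k,
                 n = length(configs),
                 anchors = attr(configs[[1]], "anchors")),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat(sprintf("shape_set: %d specimens x %d landmarks (groups: %s)\n",
              x$n, x$k, paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

# ordinary Procrustes alignment of one centered unit-size config onto a
# reference (rotation only); both as k x 2 matrices
.opa_rotate <- function(x, ref) {
  zx <- complex(real = x[, 1], imaginary = x[, 2])
  zr <- complex(real = ref[, 1], imaginary = ref[, 2])
  w <- sum(Conj(zx) * zr)
  rot <- w / Mod(w)
  zx <- zx * rot
  cbind(Re(zx), Im(zx))
}

# full Procrustes distance between two configs (centered, unit size)
.procrustes_dist <- function(x, y) {
  xa <- .opa_rotate(x, y)
  sqrt(sum((xa - y)^2))
}

# center and scale a raw config to unit centroid size
.center_scale <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  x / sqrt(sum(x^2))
}
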