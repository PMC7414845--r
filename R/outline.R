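#' Crown outlines and semilandmark resampling
#'
#' An occlusal-view crown outline is an ordered closed 2D polygon with two
#' homologous anchor landmarks that split it into two curves. For shape
#' analysis the outline is resampled to a fixed configuration: the two
#' anchors plus 80 semilandmarks equally spaced by arc length on curve 1
#' (anchor 1 to anchor 2) and 60 on curve 2 (anchor 2 back to anchor 1),
#' 142 points in all.
#'
#' @name outlines
NULL

#' Construct an outline
#'
#' @param points n x 2 matrix of ordered boundary points (closed polygon;
#'   do not repeat the first point).
#' @param anchors indices of the two homologous anchor landmarks.
#' @param specimen_id specimen label.
#' @param group group label or `"unknown"`.
#' @return object of class `outline2d`.
#' @export
outline2d <- function(points, anchors, specimen_id = "specimen",
                      group = "unknown") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 4L, length(anchors) == 2L)
  anchors <- as.integer(anchors)
  if (anchors[1] == anchors[2]) .pc_stop("anchor landmarks must be distinct")
  if (any(anchors < 1L | anchors > nrow(points)))
    .pc_stop("anchor indices out of range")
  structure(list(points = points, anchors = anchors,
                 specimen_id = specimen_id, group = group),
            class = "outline2d")
}

#' @export
print.outline2d <- function(x, ...) {
  cat(sprintf("outline2d '%s' (%s): %d points, anchors at %d, %d\n",
              x$specimen_id, x$group, nrow(x$points), x$anchors[1],
              x$anchors[2]))
  invisible(x)
}

# signed polygon area (positive = counter-clockwise)
.signed_area <- function(p) {
  q <- rbind(p, p[1, ])
  sum(q[-nrow(q), 1] * q[-1, 2] - q[-1, 1] * q[-nrow(q), 2]) / 2
}

#' Semilandmark scheme configuration
#'
#' @param counts semilandmarks per curve (default `c(80, 60)`).
#' @param mode sliding objective: `"bending_energy"` (thin-plate-spline
#'   bending energy against the Procrustes mean; default) or
#'   `"procrustes_distance"`.
#' @param max_iter maximum slide/re-superimpose iterations.
#' @param tol relative objective change that counts as converged.
#' @return list of class `semilandmark_config`.
#' @export
semilandmark_config <- function(counts = c(80, 60),
                                mode = c("bending_energy",
                                         "procrustes_distance"),
                                max_iter = 10, tol = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(length(counts) == 2L)
  if (any(counts < 2)) .pc_stop("each curve needs >= 2 semilandmarks")
  structure(list(counts = as.integer(counts), mode = mode,
                 max_iter = max_iter, tol = tol),
            class = "semilandmark_config")
}

# m interior points equally spaced by arc length along an open polyline
.resample_polyline <- function(pts, m) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) .pc_stop("zero-length curve between anchors")
  targets <- total * seq_len(m) / (m + 1)
  x <- stats::approx(cum, pts[, 1], xout = targets)$y
  y <- stats::approx(cum, pts[, 2], xout = targets)$y
  cbind(x, y)
}

#' Resample an outline to the fixed semilandmark configuration
#'
#' Orientation is normalized to counter-clockwise; right-side (mirrored)
#' outlines can be reflected first so left and right teeth share one
#' homology frame. The two anchors are retained exactly; semilandmarks are
#' equally spaced by arc length on each curve, exclusive of the anchors.
#'
#' @param o an [outline2d].
#' @param cfg a [semilandmark_config].
#' @param mirror reflect the outline (for right teeth) before resampling.
#' @return a `(counts[1] + counts[2] + 2) x 2` matrix in the order anchor 1,
#'   curve-1 semilandmarks, anchor 2, curve-2 semilandmarks; attributes
#'   `anchors` (their row indices), `specimen_id`, `group`.
#' @export
resample_outline <- function(o, cfg = semilandmark_config(),
                             mirror = FALSE) {
  stopifnot(inherits(o, "outline2d"), inherits(cfg, "semilandmark_config"))
  p <- o$points
  a <- o$anchors
  if (mirror) p[, 2] <- -p[, 2]
  if (.signed_area(p) < 0) {
    p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    a <- nrow(p) + 1L - a
  }
  n <- nrow(p)
  path_ids <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1:to)
  }
  c1 <- p[path_ids(a[1], a[2]), , drop = FALSE]
  c2 <- p[path_ids(a[2], a[1]), , drop = FALSE]
  out <- rbind(p[a[1], ], .resample_polyline(c1, cfg$counts[1]),
               p[a[2], ], .resample_polyline(c2, cfg$counts[2]))
  rownames(out) <- NULL
  attr(out, "anchors") <- c(1L, cfg$counts[1] + 2L)
  attr(out, "specimen_id") <- o$specimen_id
  attr(out, "group") <- o$group
  out
}

#' Read / write outlines in TPS format
#'
#' Minimal TPS (tpsDig-style) support: `LM=` blocks of landmark
#' coordinates, optional `CURVES=`/`POINTS=` records, and `ID=` fields.
#' This package writes each outline as one record with `LM=2` (the two
#' anchors) followed by one curve holding the full outline point list.
#'
#' @param outlines list of [outline2d] objects.
#' @param path file path.
#' @return `path` invisibly, or a list of [outline2d].
#' @export
write_tps <- function(outlines, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (o in outlines) {
    a <- o$points[o$anchors, , drop = FALSE]
    writeLines(c("LM=2",
                 sprintf("%.6f %.6f", a[, 1], a[, 2]),
                 "CURVES=1",
                 sprintf("POINTS=%d", nrow(o$points)),
                 sprintf("%.6f %.6f", o$points[, 1], o$points[, 2]),
                 sprintf("ID=%s", o$specimen_id),
                 sprintf("COMMENT=group:%s", o$group)), con)
  }
  invisible(path)
}

#' @rdname write_tps
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    nlm <- as.integer(sub("^LM=", "", blk[1]))
    lm <- do.call(rbind, lapply(blk[1 + seq_len(nlm)], function(s)
      as.numeric(strsplit(s, "\\s+")[[1]])))
    rest <- blk[-(1:(nlm + 1L))]
    pts_i <- grep("^POINTS=", rest)
    pts <- NULL
    if (length(pts_i)) {
      np <- as.integer(sub("^POINTS=", "", rest[pts_i[1]]))
      pts <- do.call(rbind, lapply(rest[pts_i[1] + seq_len(np)], function(s)
        as.numeric(strsplit(s, "\\s+")[[1]])))
    }
    id_i <- grep("^ID=", rest)
    id <- if (length(id_i)) sub("^ID=", "", rest[id_i[1]]) else
      sprintf("tps_%d", i)
    g_i <- grep("^COMMENT=group:", rest)
    grp <- if (length(g_i)) sub("^COMMENT=group:", "", rest[g_i[1]]) else
      "unknown"
    if (is.null(pts)) pts <- lm
    anchors <- vapply(seq_len(min(2L, nrow(lm))), function(k)
      which.min(colSums((t(pts) - lm[k, ])^2)), integer(1))
    if (length(anchors) < 2L) anchors <- c(1L, max(2L, nrow(pts) %/% 2L))
    outline2d(pts, anchors, specimen_id = id, group = grp)
  })
}

#' Centroid size of a point configuration
#'
#' Square root of the summed squared distances of the points to their
#' centroid: the size variable carried through Procrustes analysis and
#' used in allometry tests.
#'
#' @param x k x 2 matrix.
#' @return numeric scalar.
#' @export
centroid_size <- function(x) {
  x <- as.matrix(x)
  sqrt(sum(sweep(x, 2, colMeans(x))^2))
}
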