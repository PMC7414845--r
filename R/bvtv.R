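#' Epiphyseal BV/TV maturity screen
#'
#' Skeletally immature canids have more porous trabecular and cortical
#' bone, so the bone-volume over total-volume ratio of the proximal
#' metacarpal epiphysis separates young from adult individuals. The
#' epiphysis is delimited by a separation plane (transversal, tangent to
#' the distal ridge of the articular facet; its positive side is
#' proximal). BV is the bone voxel volume on the proximal side; TV is the
#' volume inside the outer bone envelope there, obtained by morphological
#' closing of the bone mask (ball radius a configurable fraction of the
#' epiphysis diameter) so that marrow spaces and trabecular voids count
#' toward TV.
#'
#' @param labels a [label_volume] with [bone_semantics()].
#' @param separation a [plane]; the proximal epiphysis is its positive side.
#' @param closing_frac closing radius as a fraction of the epiphysis
#'   diameter (default 0.05).
#' @param threshold BV/TV below which the maturity call is "immature". The
#'   default 0.65 is the midpoint of the default young (porosity 0.5) and
#'   adult (porosity 0.2) phantom cohorts.
#' @return list of class `bvtv_result`: `BV`, `TV` (mm^3), `ratio`,
#'   `maturity_call` ("adult"/"immature"), `threshold`, `closing_radius_vox`.
#' @export
bv_tv <- function(labels, separation, closing_frac = 0.05,
                  threshold = 0.65) {
  stopifnot(inherits(labels, "label_volume"), inherits(separation, "pc_plane"))
  vx <- labels$voxel_mm
  bone <- .tissue_mask(labels, "bone")
  if (!any(bone)) .pc_stop("no bone voxels in the volume")
  co <- .voxel_coords(labels, bone)
  h_all <- .plane_height(co, separation)
  if (!any(h_all > 0)) .pc_stop("no bone on the proximal side of the plane")
  diam <- max(apply(co, 2, function(x) diff(range(x)))) / vx
  r <- max(1L, as.integer(round(closing_frac * diam)))
  env <- .close_mask(bone, r)
  # proximal half-space mask over the full grid
  d <- dim(labels$data)
  all_co <- .voxel_coords(labels, seq_len(prod(d)))
  prox <- array(.plane_height(all_co, separation) > 0, d)
  BV <- sum(bone & prox) * vx^3
  TV <- sum(env & prox) * vx^3
  ratio <- BV / TV
  structure(list(BV = BV, TV = TV, ratio = ratio,
                 maturity_call = if (ratio >= threshold) "adult" else "immature",
                 threshold = threshold, closing_radius_vox = r),
            class = "bvtv_result")
}

#' @export
print.bvtv_result <- function(x, ...) {
  cat(sprintf("BV/TV = %.3f (BV %.2f mm^3, TV %.2f mm^3): %s (threshold %.2f)\n",
              x$ratio, x$BV, x$TV, x$maturity_call, x$threshold))
  invisible(x)
}
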