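#' Crown-slice tissue analysis of the lower carnassial
#'
#' The percent of crown dentine is measured in a 3D tooth slice bounded by
#' two cross-sections parallel to the cervix plane: cross-section 1 through
#' the lowest point of the occlusal valley (fossa) between the paraconid
#' and the protoconid, and cross-section 2 at the level where the two cusps
#' separate - operationalized as the lowest cervix-parallel level at which
#' the enamel cap above it splits into two 26-connected components. The
#' percent of crown dentine is
#' \deqn{Vcdp/Vc \times 100 = \frac{V_{dentine}}{V_{dentine}+V_{enamel}} \times 100}
#' computed on the voxels strictly between the two planes.
#'
#' @name crown_slice
NULL

# project voxel coordinates into plane frame: (u, v, h)
.plane_frame <- function(points, pl) {
  B <- .plane_basis(pl)
  cbind(u = drop(points %*% B[, 1]), v = drop(points %*% B[, 2]),
        h = .plane_height(points, pl))
}

# find the two cusp apices among enamel voxels: the top-decile (by height)
# enamel voxels are split into two clusters by a deterministic farthest-
# point assignment; each apex is its cluster's highest voxel.
.find_apices <- function(coords, h, voxel_mm, min_sep_vox = 4) {
  top <- h >= stats::quantile(h, 0.90)
  pts <- coords[top, , drop = FALSE]
  ht <- h[top]
  i1 <- which.max(ht)
  d1 <- sqrt(rowSums(sweep(pts, 2, pts[i1, ])^2))
  i2 <- which.max(d1)
  for (it in 1:5) {
    d2 <- sqrt(rowSums(sweep(pts, 2, pts[i2, ])^2))
    g1 <- d1 <= d2
    j1 <- which(g1)[which.max(ht[g1])]
    j2 <- which(!g1)[which.max(ht[!g1])]
    if (identical(j1, i1) && identical(j2, i2)) break
    i1 <- j1; i2 <- j2
    d1 <- sqrt(rowSums(sweep(pts, 2, pts[i1, ])^2))
  }
  sep <- sqrt(sum((pts[i1, ] - pts[i2, ])^2))
  if (!length(i2) || sep < min_sep_vox * voxel_mm)
    .pc_stop("no two distinct cusp apices found (separation %.2f mm): single-cusped tooth?",
             sep)
  rbind(pts[i1, ], pts[i2, ])
}

#' Extract the crown slice between the fossa floor and the cusp split level
#'
#' Works for an arbitrarily oriented cervix plane: all geometry is done in
#' signed heights above the plane. The fossa floor is the minimum of the
#' occlusal surface along the straight segment between the two cusp apices
#' (surface height sampled in a small-radius tube around the segment); the
#' split level is found by bisection on the height at which the enamel
#' voxels above it fall into two 26-connected components separating the
#' apices.
#'
#' @param labels a [label_volume] with [tooth_semantics()].
#' @param cervix a [plane] fitted to the cervix, positive side occlusal.
#' @param tube_mm sampling radius around the inter-apex segment.
#' @return object of class `crown_slice`: list with `section1`, `section2`
#'   (planes), `h1`, `h2` (their heights above the cervix plane's offset,
#'   mm), per-tissue voxel counts in and out of the slice, volumes in mm^3,
#'   `voxel_mm`, and `in_slice` (index vector of slice voxels).
#' @export
extract_crown_slice <- function(labels, cervix, tube_mm = NULL) {
  stopifnot(inherits(labels, "label_volume"), inherits(cervix, "pc_plane"))
  vx <- labels$voxel_mm
  if (is.null(tube_mm)) tube_mm <- 1.6 * vx
  enam <- which(.tissue_mask(labels, "enamel"))
  dent <- which(.tissue_mask(labels, "dentine"))
  if (!length(enam)) .pc_stop("no enamel voxels in the volume")
  ce <- .voxel_coords(labels, enam)
  he <- .plane_height(ce, cervix)
  apices <- .find_apices(ce, he, vx)
  # fossa floor: min of the surface height along the inter-apex segment
  B <- .plane_basis(cervix)
  tooth <- c(enam, dent)
  ct <- rbind(ce, .voxel_coords(labels, dent))
  fr <- .plane_frame(ct, cervix)
  a_uv <- .plane_frame(apices, cervix)[, 1:2, drop = FALSE]
  tseq <- seq(0.12, 0.88, length.out = 64)
  floor_h <- vapply(tseq, function(t) {
    p <- (1 - t) * a_uv[1, ] + t * a_uv[2, ]
    # surface height of the voxel column containing the sample point,
    # widening the search box only if that column is empty
    for (hw in c(0.75 * vx, 1.1 * vx, tube_mm)) {
      near <- abs(fr[, 1] - p[1]) <= hw & abs(fr[, 2] - p[2]) <= hw
      if (any(near)) return(max(fr[near, 3]))
    }
    NA_real_
  }, numeric(1))
  if (all(is.na(floor_h)))
    .pc_stop("no tooth voxels along the inter-apex segment")
  h1 <- min(floor_h, na.rm = TRUE)
  # split level by bisection over enamel-above-level connectivity
  d <- dim(labels$data)
  earr_idx <- enam
  ih <- he
  apex_h <- .plane_height(apices, cervix)
  split_at <- function(L) {
    keep <- ih > L
    if (sum(keep) < 2L) return(TRUE)
    m <- array(FALSE, d)
    m[earr_idx[keep]] <- TRUE
    labm <- .components(m)
    # locate the components containing each apex's nearest enamel voxel
    comp <- vapply(1:2, function(k) {
      dd <- rowSums(sweep(ce[keep, , drop = FALSE], 2, apices[k, ])^2)
      labm[earr_idx[keep][which.min(dd)]]
    }, numeric(1))
    comp[1] != comp[2]
  }
  lo <- h1; hi <- min(apex_h) - vx
  if (hi <= lo) .pc_stop("cusp apices do not rise above the fossa floor")
  if (split_at(lo))
    .pc_stop("enamel cap already split at the fossa floor: single-cusped or damaged tooth")
  if (!split_at(hi))
    .pc_stop("enamel cap never splits below the apices: single-cusped tooth?")
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    if (split_at(mid)) hi <- mid else lo <- mid
  }
  h2 <- hi
  if (h2 <= h1) .pc_stop("cross-section 2 at or below cross-section 1")
  in_slice_e <- enam[he > h1 & he < h2]
  hd <- .plane_height(ct[(length(enam) + 1):nrow(ct), , drop = FALSE], cervix)
  in_slice_d <- dent[hd > h1 & hd < h2]
  counts <- c(dentine = length(in_slice_d), enamel = length(in_slice_e))
  out_counts <- c(dentine = length(dent) - counts[["dentine"]],
                  enamel = length(enam) - counts[["enamel"]])
  structure(list(
    section1 = plane(cervix$normal, cervix$offset + h1),
    section2 = plane(cervix$normal, cervix$offset + h2),
    h1 = h1, h2 = h2,
    counts = counts, out_counts = out_counts,
    volumes_mm3 = counts * vx^3,
    voxel_mm = vx,
    in_slice = c(in_slice_d, in_slice_e),
    apices_mm = apices,
    tooth_breadth_mm = diff(range(fr[, 2]))),
    class = "crown_slice")
}

#' Percent of crown dentine in a slice
#'
#' @param slice a `crown_slice` from [extract_crown_slice].
#' @return list of class `tissue_proportions`: `Vc` (dentine+enamel, mm^3),
#'   `Vcdp` (dentine, mm^3), `percent` (Vcdp/Vc x 100), `tooth_breadth_mm`.
#' @export
dentine_percent <- function(slice) {
  stopifnot(inherits(slice, "crown_slice"))
  Vcdp <- unname(slice$volumes_mm3[["dentine"]])
  Vc <- unname(sum(slice$volumes_mm3))
  if (Vc <= 0) .pc_stop("empty crown slice (Vc = 0)")
  structure(list(Vc = Vc, Vcdp = Vcdp, percent = 100 * Vcdp / Vc,
                 tooth_breadth_mm = slice$tooth_breadth_mm),
            class = "tissue_proportions")
}

#' @export
print.tissue_proportions <- function(x, ...) {
  cat(sprintf("crown slice: Vcdp %.3f mm^3 / Vc %.3f mm^3 = %.1f%% dentine (breadth %.2f mm)\n",
              x$Vcdp, x$Vc, x$percent, x$tooth_breadth_mm))
  invisible(x)
}

#' Occlusal wear screening
#'
#' Wear shows in virtual models as flat facets where the occlusal enamel is
#' locally thinned or absent. Above cross-section 2 (the cusp tips), the
#' tooth is binned into columns along the cervix-plane normal; in each
#' column whose topmost tissue voxel lies above the section the enamel run
#' from the surface inward is measured. The tooth is flagged worn if any
#' column exposes dentine at the surface (thickness 0) or if the minimum
#' thickness falls below `frac` of the median column thickness.
#'
#' @param labels a [label_volume] with [tooth_semantics()].
#' @param cervix cervix [plane].
#' @param section2 optional precomputed cross-section-2 [plane]; computed
#'   via [extract_crown_slice] when missing.
#' @param frac thinness fraction for the wear call (default 0.5).
#' @return list of class `wear_report`: `worn`, `min_occlusal_enamel_frac`
#'   (min/median column thickness; 0 when dentine is exposed),
#'   `exposed_fraction` (share of occlusal columns with no surface enamel),
#'   `severity` (1 - min fraction), `median_thickness_mm`.
#' @export
detect_wear <- function(labels, cervix, section2 = NULL, frac = 0.5) {
  stopifnot(inherits(labels, "label_volume"))
  vx <- labels$voxel_mm
  if (is.null(section2)) {
    sl <- try(extract_crown_slice(labels, cervix), silent = TRUE)
    if (inherits(sl, "try-error"))
      return(structure(list(worn = TRUE, min_occlusal_enamel_frac = 0,
                            exposed_fraction = 1, severity = 1,
                            median_thickness_mm = 0),
                       class = "wear_report"))
    section2 <- sl$section2
  }
  tooth_idx <- which(labels$data != labels$semantics[["background"]])
  if (!any(labels$data == labels$semantics[["enamel"]]))
    return(structure(list(worn = TRUE, min_occlusal_enamel_frac = 0,
                          exposed_fraction = 1, severity = 1,
                          median_thickness_mm = 0),
                     class = "wear_report"))
  co <- .voxel_coords(labels, tooth_idx)
  fr <- .plane_frame(co, section2)
  lab <- labels$data[tooth_idx]
  iu <- round(fr[, 1] / vx); iv <- round(fr[, 2] / vx)
  is_en <- lab == labels$semantics[["enamel"]]
  sp <- split(seq_along(tooth_idx), paste(iu, iv))
  # per occlusal column: the surface voxel above cs2 (skipping the lowest
  # band, which belongs to the section boundary, not the occlusal surface)
  surf <- vapply(sp, function(ii) {
    j <- ii[which.max(fr[ii, 3])]
    if (fr[j, 3] <= 2.5 * vx) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(iu[j], iv[j], fr[j, 3], j)
  }, numeric(4))
  surf <- surf[, !is.na(surf[3, ]), drop = FALSE]
  if (!ncol(surf)) .pc_stop("no tooth columns above cross-section 2")
  # occlusal enamel thickness per column: distance from the surface voxel
  # to the nearest dentine voxel (0 where dentine is exposed)
  dent_co <- co[lab == labels$semantics[["dentine"]], , drop = FALSE]
  if (!nrow(dent_co)) .pc_stop("no dentine voxels in the volume")
  thick <- vapply(seq_len(ncol(surf)), function(c_) {
    j <- surf[4, c_]
    if (!is_en[j]) return(0)
    p0 <- co[j, ]
    sqrt(min((dent_co[, 1] - p0[1])^2 + (dent_co[, 2] - p0[2])^2 +
               (dent_co[, 3] - p0[3])^2))
  }, numeric(1))
  med <- stats::median(thick[thick > 0])
  if (!is.finite(med) || med == 0) {
    out <- list(worn = TRUE, min_occlusal_enamel_frac = 0,
                exposed_fraction = 1, severity = 1, median_thickness_mm = 0)
  } else {
    mf <- min(thick) / med
    out <- list(worn = any(thick == 0) || mf < frac,
                min_occlusal_enamel_frac = mf,
                exposed_fraction = mean(thick == 0),
                severity = 1 - mf,
                median_thickness_mm = med)
  }
  structure(out, class = "wear_report")
}

#' Cervix point extraction
#'
#' The cervix is taken as the enamel margin at the enamel-dentine junction:
#' enamel voxels that touch (6-neighbourhood) both dentine and background.
#'
#' @param labels a [label_volume] with [tooth_semantics()].
#' @return n x 3 matrix of voxel-centre coordinates (mm).
#' @export
extract_cervix_points <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  en <- .tissue_mask(labels, "enamel")
  de <- .tissue_mask(labels, "dentine")
  bg <- labels$data == labels$semantics[["background"]]
  touch_de <- .dilate1(de) & en
  touch_bg <- .dilate1(bg) & en
  idx <- which(touch_de & touch_bg)
  if (!length(idx)) .pc_stop("no cervix voxels found (no enamel margin)")
  .voxel_coords(labels, idx)
}

# similarity (rotation + translation + uniform scale) fit of matched point
# sets: Umeyama least squares, mapping X onto Y
.umeyama <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  D <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) D[3, 3] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  varx <- mean(rowSums(Xc^2))
  s <- sum(diag(diag(sv$d) %*% D)) / varx
  t <- my - s * drop(R %*% mx)
  list(R = R, s = s, t = t)
}

# similarity ICP of an (incomplete) point set onto a complete reference
.icp_similarity <- function(X, Y, iters = 15) {
  # init: align TLS plane normals and centroids, match RMS radius
  px <- fit_cervix_plane(X); py <- fit_cervix_plane(Y)
  axis <- c(px$normal[2] * py$normal[3] - px$normal[3] * py$normal[2],
            px$normal[3] * py$normal[1] - px$normal[1] * py$normal[3],
            px$normal[1] * py$normal[2] - px$normal[2] * py$normal[1])
  ca <- sum(px$normal * py$normal)
  if (sqrt(sum(axis^2)) < 1e-12) {
    R <- diag(3) * sign(ca)
    if (ca < 0) R[1, 1] <- -R[1, 1] # keep det +1 for antiparallel normals
  } else {
    axis <- axis / sqrt(sum(axis^2))
    sa <- sqrt(max(0, 1 - ca^2))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sa * K + (1 - ca) * K %*% K
  }
  mx <- colMeans(X); my <- colMeans(Y)
  s <- sqrt(mean(rowSums(sweep(Y, 2, my)^2)) /
              mean(rowSums(sweep(X, 2, mx)^2)))
  tr <- my - s * drop(R %*% mx)
  fit <- list(R = R, s = s, t = tr)
  for (i in seq_len(iters)) {
    Xt <- sweep(s * X %*% t(R), 2, tr, `+`)
    nn <- apply(Xt, 1, function(p)
      which.min(colSums((t(Y) - p)^2)))
    fit <- .umeyama(X, Y[nn, , drop = FALSE])
    R <- fit$R; s <- fit$s; tr <- fit$t
  }
  fit$rms <- sqrt(mean(rowSums((sweep(s * X %*% t(R), 2, tr, `+`) -
                                  Y[nn, , drop = FALSE])^2)))
  fit
}

#' Dentine percent of a cervix-broken tooth via reference alignment
#'
#' When the cervix is partly broken its cross-section orientation cannot be
#' fitted directly, so the preserved cervix point set is aligned (similarity
#' transform: rotation, translation, uniform scale, least squares via
#' iterated closest points) to the cervix of each of three intact reference
#' teeth. Each alignment re-orients the target with the reference's cervix
#' plane, the crown slice is extracted under that orientation, and the
#' dentine percent computed - yielding three estimates of the broken
#' specimen's value.
#'
#' @param target a [label_volume]: the broken tooth.
#' @param references list of exactly 3 intact [label_volume]s.
#' @param min_points minimum preserved cervix points required per alignment.
#' @return list of 3 `tissue_proportions` (one per reference), with
#'   attribute `alignments` (the fitted transforms).
#' @export
reconstruct_broken_cervix <- function(target, references, min_points = 40) {
  stopifnot(inherits(target, "label_volume"))
  if (length(references) != 3L)
    .pc_stop("exactly 3 reference teeth are required (got %d)",
             length(references))
  cerv_t <- extract_cervix_points(target)
  if (nrow(cerv_t) < min_points)
    .pc_stop("only %d preserved cervix points (minimum %d)", nrow(cerv_t),
             min_points)
  ests <- vector("list", 3L)
  fits <- vector("list", 3L)
  for (k in 1:3) {
    ref <- references[[k]]
    stopifnot(inherits(ref, "label_volume"))
    cerv_r <- extract_cervix_points(ref)
    fit <- .icp_similarity(cerv_t, cerv_r)
    if (fit$rms > 10 * ref$voxel_mm)
      .pc_stop("cervix alignment to reference %d failed (rms %.2f mm)", k,
               fit$rms)
    # reference cervix plane, oriented toward the reference's enamel
    occl <- colMeans(.voxel_coords(ref, .tissue_mask(ref, "enamel")))
    pl_r <- fit_cervix_plane(cerv_r, toward = occl)
    # pull the plane back into target coordinates:
    # x_r = s R x_t + t  =>  n_r . x_r - d = s (R'n_r) . x_t + n_r.t - d
    n_t <- drop(t(fit$R) %*% pl_r$normal)
    d_t <- (pl_r$offset - sum(pl_r$normal * fit$t)) / fit$s
    # re-orient toward the target's own occlusal (enamel) side: a ring-
    # symmetric ICP solution can come back flipped
    occl_t <- colMeans(.voxel_coords(target, .tissue_mask(target, "enamel")))
    if (sum(n_t * occl_t) - d_t < 0) { n_t <- -n_t; d_t <- -d_t }
    sl <- extract_crown_slice(target, plane(n_t, d_t))
    ests[[k]] <- dentine_percent(sl)
    fits[[k]] <- fit
  }
  attr(ests, "alignments") <- fits
  ests
}
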