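#' Shape PCA and between-group PCA
#'
#' Ordinary PCA summarizes the total shape variation of a Procrustes-
#' aligned sample. Between-group PCA (bgPCA) instead takes the principal
#' axes of the *group mean* shapes (groups weighted equally) and projects
#' all individuals onto them: with g groups there are at most g - 1
#' between-group axes. Specimens of unknown affiliation are projected a
#' posteriori without influencing the means. Residual axes (PCA of the
#' within-group remainder, orthogonal to the between-group axes) can be
#' appended and are flagged as such.
#'
#' @name bgpca_models
NULL

# vectorize a shape_set into an n x 2k matrix
.shape_matrix <- function(shapes) {
  n <- shapes$n; k <- shapes$k
  t(vapply(seq_len(n), function(i) c(shapes$coords[, , i]),
           numeric(2 * k)))
}

#' Principal component analysis of shapes
#'
#' @param shapes a `shape_set` from [gpa()] or [slide_semilandmarks()].
#' @return object of class `shape_pca`: `axes` (2k x r), `scores` (n x r),
#'   `var` (eigenvalues), `var_frac` (fractions over the retained axes),
#'   `center` (grand mean vector). Retained axes are the non-trivial ones,
#'   at most `min(n - 1, 2k - 4)`.
#' @export
pca_shapes <- function(shapes) {
  stopifnot(inherits(shapes, "shape_set"))
  if (shapes$n < 3L) .pc_stop("PCA needs >= 3 specimens")
  X <- .shape_matrix(shapes)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  r <- min(shapes$n - 1L, 2L * shapes$k - 4L)
  pos <- which(sv$d[seq_len(r)]^2 > 1e-12 * sv$d[1]^2)
  ev <- sv$d[pos]^2 / (shapes$n - 1)
  structure(list(axes = sv$v[, pos, drop = FALSE],
                 scores = Xc %*% sv$v[, pos, drop = FALSE],
                 var = ev, var_frac = ev / sum(ev), center = ctr,
                 shapes = shapes),
            class = "shape_pca")
}

#' Between-group principal component analysis
#'
#' @param shapes a `shape_set`.
#' @param groups group labels (defaults to the set's own); specimens
#'   labelled `"unknown"` are excluded from the group means but still
#'   receive scores.
#' @param residual_axes append PCA axes of the within-group residuals,
#'   flagged `"residual"`.
#' @return object of class `bgpca_model`: `axes` (2k x r), `axis_type`
#'   (`"between"`/`"residual"`), `scores` (training specimens), `groups`,
#'   `group_means` (in score space), `grand_mean`, `consensus` (GPA mean
#'   shape), `csize`, `mode` (sliding mode used upstream, if any).
#' @export
bgpca <- function(shapes, groups = NULL, residual_axes = TRUE) {
  stopifnot(inherits(shapes, "shape_set"))
  if (is.null(groups)) groups <- shapes$groups
  train <- groups != "unknown"
  gl <- unique(groups[train])
  if (length(gl) < 2L) .pc_stop("bgPCA needs >= 2 groups")
  X <- .shape_matrix(shapes)
  sizes <- table(factor(groups[train], levels = gl))
  if (any(sizes == 1L))
    .pc_warn("group(s) with a single specimen: %s (mean = that specimen)",
             paste(names(sizes)[sizes == 1L], collapse = ", "))
  M <- t(vapply(gl, function(g)
    colMeans(X[train & groups == g, , drop = FALSE]), numeric(ncol(X))))
  grand <- colMeans(M)                      # groups weighted equally
  sv <- svd(sweep(M, 2, grand))
  nb <- sum(sv$d^2 > 1e-12 * max(sv$d^2, 1e-300))
  nb <- min(nb, length(gl) - 1L)
  axes <- sv$v[, seq_len(nb), drop = FALSE]
  axis_type <- rep("between", nb)
  if (residual_axes) {
    Xc <- sweep(X[train, , drop = FALSE], 2, grand)
    resid <- Xc - Xc %*% axes %*% t(axes)
    sv2 <- svd(resid)
    nr <- min(sum(train) - 1L, 2L * shapes$k - 4L) - nb
    nr <- min(nr, sum(sv2$d^2 > 1e-9 * max(sv2$d^2, 1e-300)))
    if (nr > 0L) {
      axes <- cbind(axes, sv2$v[, seq_len(nr), drop = FALSE])
      axis_type <- c(axis_type, rep("residual", nr))
    }
  }
  scores <- sweep(X, 2, grand) %*% axes
  rownames(scores) <- shapes$specimen_ids
  gm_scores <- sweep(M, 2, grand) %*% axes
  rownames(gm_scores) <- gl
  structure(list(axes = axes, axis_type = axis_type,
                 scores = scores[train, , drop = FALSE],
                 all_scores = scores,
                 groups = groups[train], group_labels = gl,
                 group_means = gm_scores, grand_mean = grand,
                 consensus = shapes$mean, csize = shapes$csize,
                 anchors = shapes$anchors,
                 mode = attr(shapes, "mode"), k = shapes$k),
            class = "bgpca_model")
}

#' @export
print.bgpca_model <- function(x, ...) {
  cat(sprintf("bgPCA model: %d groups (%s), %d between-group + %d residual axes\n",
              length(x$group_labels), paste(x$group_labels, collapse = ", "),
              sum(x$axis_type == "between"),
              sum(x$axis_type == "residual")))
  invisible(x)
}

#' Project unknown specimens onto a fitted bgPCA model
#'
#' Each unknown configuration is centred, scaled to unit centroid size and
#' rotated onto the model's consensus by ordinary Procrustes alignment
#' (optionally slid once against the consensus when the model was fitted
#' from slid semilandmarks), then projected onto the model axes. The model
#' itself is never refitted.
#'
#' @param model a `bgpca_model`.
#' @param configs list of k x 2 matrices (or a single matrix).
#' @param slide slide the unknowns once toward the consensus first;
#'   defaults to whether the model was built from slid shapes.
#' @return matrix of scores (one row per unknown), with attribute `csize`.
#' @export
project_unknowns <- function(model, configs, slide = NULL) {
  stopifnot(inherits(model, "bgpca_model"))
  if (is.matrix(configs)) configs <- list(configs)
  if (is.null(slide)) slide <- !is.null(model$mode)
  k <- model$k
  bad <- vapply(configs, nrow, integer(1)) != k
  if (any(bad))
    .pc_stop("landmark count mismatch: expected %d", k)
  cs <- vapply(configs, centroid_size, numeric(1))
  scores <- t(vapply(configs, function(x) {
    xa <- if (slide)
      .slide_to_reference(x, model$consensus, model$anchors,
                          if (is.null(model$mode)) "bending_energy" else model$mode)
    else .opa_rotate(.center_scale(x), model$consensus)
    drop(crossprod(c(xa) - model$grand_mean, model$axes))
  }, numeric(ncol(model$axes))))
  attr(scores, "csize") <- cs
  scores
}

#' Group assignment with typicality
#'
#' Assigns a projected specimen to the group with the nearest mean in
#' between-group score space and reports, per group, a typicality
#' probability: the fraction of that group's training specimens lying at
#' least as far from their own mean (with a (r+1)/(n+1) permutation-style
#' correction). An overlap flag marks scores falling inside the 95th
#' distance percentile of more than one group.
#'
#' @param model a `bgpca_model`.
#' @param score numeric vector of scores (only the between-group axes are
#'   used), or a matrix of one row.
#' @return list of class `group_assignment`: `label`, `typicality` (named),
#'   `overlap`, `distances` (named).
#' @export
assign_group <- function(model, score) {
  stopifnot(inherits(model, "bgpca_model"))
  nb <- which(model$axis_type == "between")
  score <- as.numeric(score)[nb]
  dists <- apply(model$group_means[, nb, drop = FALSE], 1, function(m)
    sqrt(sum((score - m)^2)))
  train_d <- lapply(model$group_labels, function(g) {
    S <- model$scores[model$groups == g, nb, drop = FALSE]
    m <- model$group_means[g, nb]
    sqrt(rowSums(sweep(S, 2, m)^2))
  })
  names(train_d) <- model$group_labels
  typ <- vapply(model$group_labels, function(g) {
    (sum(train_d[[g]] >= dists[g]) + 1) / (length(train_d[[g]]) + 1)
  }, numeric(1))
  q95 <- vapply(train_d, stats::quantile, numeric(1), probs = 0.95)
  inside <- dists <= q95
  structure(list(label = names(which.min(dists)),
                 typicality = typ, overlap = sum(inside) > 1L,
                 distances = dists),
            class = "group_assignment")
}
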