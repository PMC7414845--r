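#' Sliding semilandmarks
#'
#' Semilandmarks carry no individual homology along the outline, so their
#' exact spacing is an artifact of digitization. Sliding lets each
#' semilandmark move along the local tangent direction of its curve to
#' minimize either the thin-plate-spline bending energy between the
#' specimen and the Procrustes mean (default, the classical criterion) or
#' the Procrustes distance to the mean. Anchors stay fixed. Sliding and
#' re-superimposition alternate until the total objective stabilizes.
#'
#' @name sliding
NULL

# thin-plate-spline bending energy matrix (k x k) of a 2D reference
# configuration: upper-left block of L^{-1} with kernel U(r) = r^2 log r^2
.bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Li <- solve(L + diag(1e-12, k + 3))
  Be <- Li[1:k, 1:k]
  (Be + t(Be)) / 2
}

# unit tangent directions along a closed polygonal configuration
.tangents <- function(x) {
  k <- nrow(x)
  nxt <- c(2:k, 1)
  prv <- c(k, 1:(k - 1))
  t_ <- x[nxt, ] - x[prv, ]
  t_ / pmax(sqrt(rowSums(t_^2)), 1e-12)
}

# slide one configuration toward a reference:
# minimize (y + U t)' W (y + U t) over tangential shifts t at `free` points
.slide_one <- function(x, ref, Be, free, mode) {
  k <- nrow(x)
  tg <- .tangents(x)
  y <- c(x[, 1] - ref[, 1], x[, 2] - ref[, 2])
  m <- length(free)
  U <- matrix(0, 2 * k, m)
  U[cbind(free, seq_len(m))] <- tg[free, 1]
  U[cbind(free + k, seq_len(m))] <- tg[free, 2]
  if (mode == "bending_energy") {
    WU <- rbind(Be %*% U[1:k, ], Be %*% U[(k + 1):(2 * k), ])
    Wy <- c(Be %*% y[1:k], Be %*% y[(k + 1):(2 * k)])
  } else {
    WU <- U
    Wy <- y
  }
  A <- crossprod(U, WU)
  b <- crossprod(U, Wy)
  t_hat <- -solve(A + diag(1e-10, m), b)
  x[free, ] <- x[free, ] + tg[free, ] * drop(t_hat)
  x
}

# total objective of a set against a reference
.slide_objective <- function(coords, ref, Be, mode) {
  n <- dim(coords)[3]
  s <- 0
  for (i in seq_len(n)) {
    y <- coords[, , i] - ref
    s <- s + if (mode == "bending_energy")
      sum(y[, 1] * (Be %*% y[, 1])) + sum(y[, 2] * (Be %*% y[, 2]))
    else sum(y^2)
  }
  s
}

#' Slide semilandmarks across a sample
#'
#' @param configs list of k x 2 resampled configurations (from
#'   [resample_outline()]; anchor indices are read from their attributes,
#'   or can be supplied).
#' @param cfg a [semilandmark_config] (sliding mode, iterations, tolerance).
#' @param anchors indices of fixed landmarks; defaults to the `anchors`
#'   attribute of the first configuration.
#' @return a `shape_set` (as from [gpa()]) of the slid, re-superimposed
#'   configurations, with attributes `objective` (the per-iteration
#'   objective sequence, evaluated against the current mean after each
#'   slide), `converged`, and `mode`. If an iteration fails to decrease
#'   the objective the previous state is kept and iteration stops, so the
#'   recorded sequence is non-increasing.
#' @export
slide_semilandmarks <- function(configs, cfg = semilandmark_config(),
                                anchors = NULL) {
  stopifnot(inherits(cfg, "semilandmark_config"))
  if (length(configs) < 2L) .pc_stop("sliding needs >= 2 configurations")
  if (is.null(anchors)) anchors <- attr(configs[[1]], "anchors")
  if (is.null(anchors)) .pc_stop("no anchor indices available")
  gs <- gpa(configs)
  k <- gs$k
  free <- setdiff(seq_len(k), anchors)
  mode <- cfg$mode
  obj_seq <- numeric(0)
  state <- gs
  obj_prev <- Inf
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    ref <- state$mean
    Be <- if (mode == "bending_energy") .bending_energy_matrix(ref) else NULL
    slid <- lapply(seq_len(state$n), function(i)
      .slide_one(state$coords[, , i], ref, Be, free, mode))
    # re-superimpose the slid configurations
    new_state <- gpa(slid)
    new_state$csize <- gs$csize
    new_state$groups <- gs$groups
    new_state$specimen_ids <- gs$specimen_ids
    new_state$anchors <- anchors
    Be2 <- if (mode == "bending_energy")
      .bending_energy_matrix(new_state$mean) else NULL
    obj <- .slide_objective(new_state$coords, new_state$mean, Be2, mode)
    if (obj > obj_prev) break           # keep the previous, better state
    obj_seq <- c(obj_seq, obj)
    improved <- is.finite(obj_prev) &&
      (obj_prev - obj) <= cfg$tol * max(obj_prev, 1e-300)
    state <- new_state
    if (improved) { converged <- TRUE; break }
    obj_prev <- obj
  }
  if (!converged && length(obj_seq) == cfg$max_iter)
    .pc_warn("sliding did not converge in %d iterations", cfg$max_iter)
  attr(state, "objective") <- obj_seq
  attr(state, "converged") <- converged || length(obj_seq) < cfg$max_iter
  attr(state, "mode") <- mode
  state
}

# one-shot slide of a single configuration toward a fixed reference mean
# (used for a-posteriori specimens; the model is not refit)
.slide_to_reference <- function(x, ref, anchors, mode) {
  k <- nrow(ref)
  free <- setdiff(seq_len(k), anchors)
  Be <- if (mode == "bending_energy") .bending_energy_matrix(ref) else NULL
  xa <- .opa_rotate(.center_scale(x), ref)
  .slide_one(xa, ref, Be, free, mode)
}
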