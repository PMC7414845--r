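circle_outline <- function(n = 360) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  outline2d(cbind(cos(th), sin(th)), c(1L, n / 2 + 1L), "circle")
}

test_that("resampling a circle places semilandmarks at equal angles", {
  cfg <- semilandmark_config(counts = c(3, 3))
  conf <- resample_outline(circle_outline(), cfg)
  expect_equal(nrow(conf), 8L)
  expect_equal(attr(conf, "anchors"), c(1L, 5L))
  ang <- atan2(conf[, 2], conf[, 1]) %% (2 * pi)
  expect_equal(ang[2:4], c(pi / 4, pi / 2, 3 * pi / 4), tolerance = 1e-3)
  expect_equal(ang[6:8], c(5 * pi / 4, 3 * pi / 2, 7 * pi / 4),
               tolerance = 1e-3)
})

test_that("the full configuration is 80 + 60 semilandmarks plus 2 anchors", {
  conf <- resample_outline(circle_outline(), semilandmark_config())
  expect_equal(nrow(conf), 142L)
})

test_that("square-outline spacing matches the cumulative arc-length oracle", {
  sq <- outline2d(rbind(
    cbind(seq(0, 0.9, 0.1), 0), cbind(1, seq(0, 0.9, 0.1)),
    cbind(seq(1, 0.1, -0.1), 1), cbind(0, seq(1, 0.1, -0.1))),
    anchors = c(1L, 21L), "square")
  cfg <- semilandmark_config(counts = c(4, 4))
  conf <- resample_outline(sq, cfg)
  # oracle: brute-force cumulative arc length along each curve
  seg1 <- rbind(sq$points[1:21, ])
  cum <- c(0, cumsum(sqrt(rowSums(diff(seg1)^2))))
  targets <- max(cum) * (1:4) / 5
  ox <- approx(cum, seg1[, 1], targets)$y
  oy <- approx(cum, seg1[, 2], targets)$y
  expect_equal(conf[2:5, ], cbind(ox, oy), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("coincident anchors are rejected", {
  expect_error(outline2d(cbind(1:5, 1), c(2L, 2L)), "distinct")
})

test_that("GPA aligns rotated copies to Procrustes distance zero", {
  pop <- fx_outline_pop()$pop
  x <- resample_outline(pop$outlines[[1]], semilandmark_config())
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  y <- x %*% R * 2.3 + 5
  gs <- gpa(list(unclass(x), unclass(y)))
  expect_lt(sqrt(sum((gs$coords[, , 1] - gs$coords[, , 2])^2)), 1e-9)
})

test_that("aligned shapes have zero centroid and unit centroid size", {
  shapes <- fx_shapes()
  for (i in c(1, 20, 44)) {
    expect_equal(colMeans(shapes$coords[, , i]), c(0, 0), tolerance = 1e-9)
    expect_equal(sum(shapes$coords[, , i]^2), 1, tolerance = 1e-9)
  }
})

test_that("two-shape optimal rotation matches the SVD and grid-search oracles", {
  pop <- fx_outline_pop()$pop
  cfg <- semilandmark_config(counts = c(12, 9))
  x <- paleocanid:::.center_scale(resample_outline(pop$outlines[[1]], cfg))
  y <- paleocanid:::.center_scale(resample_outline(pop$outlines[[30]], cfg))
  xa <- paleocanid:::.opa_rotate(x, y)
  d_impl <- sqrt(sum((xa - y)^2))
  # oracle 1: Kabsch via SVD of the cross-covariance
  s <- svd(crossprod(y, x))
  R <- s$v %*% t(s$u)
  d_svd <- sqrt(sum((x %*% R - y)^2))
  # oracle 2: brute-force rotation grid at 0.01 degrees
  th <- seq(0, 2 * pi, by = 0.01 * pi / 180)
  dists <- vapply(th, function(a) {
    Ra <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    sum((x %*% Ra - y)^2)
  }, numeric(1))
  d_grid <- sqrt(min(dists))
  expect_equal(d_impl, d_svd, tolerance = 1e-9)
  expect_equal(d_impl, d_grid, tolerance = 1e-3)
})

test_that("degenerate configurations are rejected by GPA", {
  expect_error(gpa(list(matrix(1, 5, 2), matrix(1, 5, 2))), "degenerate")
})

test_that("sliding leaves identical configurations untouched and anchors fixed", {
  pop <- fx_outline_pop()$pop
  cfg <- semilandmark_config(counts = c(15, 10))
  x <- resample_outline(pop$outlines[[1]], cfg)
  same <- lapply(1:4, function(i) x)
  slid <- slide_semilandmarks(same, cfg)
  expect_lt(max(attr(slid, "objective")), 1e-18)
  # anchors unchanged by sliding in a heterogeneous sample
  confs <- resample_all(pop$outlines[1:8], cfg)
  gs <- gpa(confs)
  slid2 <- slide_semilandmarks(confs, cfg)
  a <- attr(confs[[1]], "anchors")
  # anchor landmarks are not slid: their positions equal the plain GPA
  # alignment of the same (re-superimposition may rotate the whole shape,
  # so compare inter-anchor distances, which sliding must not change)
  d_gpa <- sqrt(sum((gs$coords[a[1], , 1] - gs$coords[a[2], , 1])^2))
  d_slid <- sqrt(sum((slid2$coords[a[1], , 1] - slid2$coords[a[2], , 1])^2))
  expect_equal(d_slid, d_gpa, tolerance = 5e-3)
})

test_that("the sliding objective is non-increasing in both modes", {
  pop <- fx_outline_pop()$pop
  for (mode in c("bending_energy", "procrustes_distance")) {
    cfg <- semilandmark_config(counts = c(20, 15), mode = mode)
    # Procrustes-distance sliding may legitimately warn about hitting the
    # iteration cap while still descending; monotonicity is what matters
    slid <- suppressWarnings(
      slide_semilandmarks(resample_all(pop$outlines[1:12], cfg), cfg))
    obj <- attr(slid, "objective")
    expect_gte(length(obj), 1L)
    expect_true(all(diff(obj) <= 1e-12))
  }
})

test_that("shape PCA conserves variance and matches the eigen oracle", {
  pop <- fx_outline_pop()$pop
  cfg <- semilandmark_config(counts = c(10, 8))
  shapes <- gpa(resample_all(pop$outlines[1:5], cfg))
  p <- pca_shapes(shapes)
  X <- t(apply(shapes$coords, 3, c))
  Xc <- sweep(X, 2, colMeans(X))
  # conservation: total score variance equals total shape variance
  expect_equal(sum(apply(p$scores, 2, var)), sum(apply(Xc, 2, var)),
               tolerance = 1e-9)
  # eigendecomposition oracle
  ev <- eigen(cov(Xc), symmetric = TRUE)$values
  expect_equal(p$var, ev[seq_along(p$var)], tolerance = 1e-9)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  expect_error(pca_shapes(gpa(resample_all(pop$outlines[1:2], cfg))), ">= 3")
})

test_that("bgPCA yields g-1 between-group axes aligned with the contrast", {
  model <- fx_model()
  expect_equal(sum(model$axis_type == "between"), 1L)
  # identical group means: zero between-group separation
  pop0 <- gen_outline_population(outline_pop_config(n_per_group = c(5, 5),
                                                    within_sd = 0, seed = 2))
  sh0 <- gpa(resample_all(pop0$outlines))
  m0 <- bgpca(sh0, residual_axes = FALSE)
  expect_lt(max(abs(m0$group_means)), 1e-9)
  # synthetic contrast recovery
  cfg <- fx_outline_pop()$cfg
  sc <- semilandmark_config()
  m1 <- resample_outline(gen_group_mean_outline(cfg, 1), sc)
  m2 <- resample_outline(gen_group_mean_outline(cfg, 2), sc)
  s1 <- paleocanid:::.slide_to_reference(m1, model$consensus,
                                         model$anchors, "bending_energy")
  s2 <- paleocanid:::.slide_to_reference(m2, model$consensus,
                                         model$anchors, "bending_energy")
  v <- c(s2 - s1); v <- v / sqrt(sum(v^2))
  expect_gt(abs(sum(model$axes[, 1] * v)), 0.9)
})

test_that("a-posteriori projection is faithful and linear", {
  model <- fx_model()
  shapes <- fx_shapes()
  # a training specimen projects onto its training score
  x17 <- shapes$coords[, , 17]
  s17 <- project_unknowns(model, x17)
  # the one-shot slide against the consensus is not bit-identical to the
  # final step of the iterative fit, so allow a small absolute slack
  expect_lt(max(abs(drop(s17) - unname(model$scores[17, ]))), 5e-4)
  # the shape-space group mean projects onto the group-mean score
  X <- t(apply(shapes$coords, 3, c))
  gm <- colMeans(X[shapes$groups == "dog", ])
  sm <- project_unknowns(model, matrix(gm, ncol = 2), slide = FALSE)
  expect_equal(drop(sm)[1], unname(model$group_means["dog", 1]),
               tolerance = 1e-3)
  # midpoint of the two group means scores at the score midpoint
  gm2 <- colMeans(X[shapes$groups == "wolf", ])
  mid <- project_unknowns(model, matrix((gm + gm2) / 2, ncol = 2),
                          slide = FALSE)
  expect_equal(drop(mid)[1],
               mean(unname(model$group_means[, 1])), tolerance = 1e-3)
  expect_error(project_unknowns(model, matrix(0, 10, 2)), "mismatch")
})

test_that("group assignment reports typicality and overlap sensibly", {
  model <- fx_model()
  at_mean <- assign_group(model, model$group_means["dog", ])
  expect_identical(at_mean$label, "dog")
  expect_gt(at_mean$typicality[["dog"]], 0.9)
  far <- assign_group(model, model$group_means["dog", ] + 100)
  expect_true(all(far$typicality < 0.05))
  expect_false(far$overlap)
  mid <- assign_group(model, colMeans(model$group_means))
  expect_true(mid$overlap || all(mid$typicality < 0.5))
})

test_that("the pipeline is invariant to similarity transforms and mirroring", {
  pop <- fx_outline_pop()$pop
  cfg <- semilandmark_config(counts = c(20, 15))
  confs <- resample_all(pop$outlines[1:6], cfg)
  th <- 0.61; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  trans <- lapply(pop$outlines[1:6], function(o) {
    o$points <- o$points %*% R * 2.7
    o$points[, 1] <- o$points[, 1] + 11
    o
  })
  confs2 <- resample_all(trans, cfg)
  g1 <- gpa(confs); g2 <- gpa(confs2)
  for (i in 1:6) {
    a <- paleocanid:::.opa_rotate(g2$coords[, , i], g1$coords[, , i])
    expect_lt(max(abs(a - g1$coords[, , i])), 1e-8)
  }
  # mirrored outlines with mirror = TRUE give the same shapes
  mirr <- lapply(pop$outlines[1:6], function(o) {
    o$points[, 2] <- -o$points[, 2]
    o
  })
  confs3 <- lapply(mirr, resample_outline, cfg = cfg, mirror = TRUE)
  g3 <- gpa(confs3)
  for (i in 1:6) {
    a <- paleocanid:::.opa_rotate(g3$coords[, , i], g1$coords[, , i])
    expect_lt(max(abs(a - g1$coords[, , i])), 1e-8)
  }
})

test_that("allometry regression recovers exact and null relationships", {
  set.seed(9)
  cs <- exp(runif(30, 2, 3))
  scores <- cbind(0.5 * log(cs), rnorm(30))
  res <- suppressWarnings(test_allometry(scores, cs))  # exact fit warns
  expect_equal(res$r_squared[1], 1, tolerance = 1e-12)
  expect_equal(res$p_value[1], 0)
  expect_equal(res$slope[1], 0.5, tolerance = 1e-9)
  expect_error(test_allometry(scores, rep(3, 30)), "zero variance")
  expect_error(test_allometry(scores[1:3, ], cs[1:3]), "n >= 4")
})
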