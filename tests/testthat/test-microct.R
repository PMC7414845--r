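test_that("multi-Otsu segmentation recovers the phantom tissues", {
  ph <- fx_tooth()
  seg <- fx_tooth_seg()
  expect_gte(mean(seg$data == ph$labels$data), 0.99)
  expect_length(attr(seg, "thresholds"), 2L)
})

test_that("manual thresholds reproduce the direct thresholding oracle", {
  ph <- fx_tooth()
  thr <- c(60, 150)
  seg <- segment_tissues(ph$gray, 3, thresholds = thr)
  oracle <- (ph$gray$data > thr[1]) + (ph$gray$data > thr[2])
  expect_true(all(seg$data == oracle))
})

test_that("degenerate histograms are rejected with the offending statistic", {
  flat <- gray_volume(array(7, c(5, 5, 5)), 0.1)
  expect_error(segment_tissues(flat, 3), "sd = 0")
  twoval <- gray_volume(array(rep(c(0, 9), 60), c(6, 5, 4)), 0.1)
  expect_error(segment_tissues(twoval, 3), "distinct")
})

test_that("total-least-squares plane fit is exact on planar points", {
  set.seed(1)
  pts <- cbind(runif(40, 0, 9), runif(40, 0, 7), 5)
  pl <- fit_cervix_plane(pts, toward = c(0, 0, 10))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$offset, 5, tolerance = 1e-12)
  expect_error(fit_cervix_plane(pts[1:2, ]), ">= 3")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_cervix_plane(line), "collinear")
})

test_that("noisy cervix points still give the true plane orientation", {
  set.seed(2)
  th <- runif(300, 0, 2 * pi)
  pts <- cbind(3 + 2.5 * cos(th), 2 + 1.5 * sin(th),
               4 + rnorm(300, 0, 0.05))
  pl <- fit_cervix_plane(pts, toward = c(3, 2, 99))
  ang <- acos(min(1, sum(pl$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("crown-slice planes land within one voxel of the phantom truth", {
  ph <- fx_tooth()
  sl <- fx_tooth_slice()
  vx <- ph$labels$voxel_mm
  expect_lte(abs(sl$section1$offset - ph$truth$h1_mm), vx)
  expect_lte(abs(sl$section2$offset - ph$truth$h2_mm), vx)
})

test_that("slice and out-of-slice tissue counts partition the tooth", {
  ph <- fx_tooth()
  seg <- fx_tooth_seg()
  sl <- fx_tooth_slice()
  expect_equal(sl$counts[["dentine"]] + sl$out_counts[["dentine"]],
               sum(seg$data == 1))
  expect_equal(sl$counts[["enamel"]] + sl$out_counts[["enamel"]],
               sum(seg$data == 2))
})

test_that("single-cusped teeth are rejected by the slice protocol", {
  ph1 <- gen_tooth_phantom(tooth_phantom_config(
    cusp_height_mm = c(0.45, 3.0), enamel_thickness_mm = 0.25, seed = 5))
  expect_error(extract_crown_slice(ph1$labels, ph1$truth$cervix_plane),
               "single-cusp")
})

test_that("dentine percent follows its formula and the voxel-count oracle", {
  fake <- structure(list(counts = c(dentine = 750, enamel = 250),
                         volumes_mm3 = c(dentine = 75, enamel = 25),
                         tooth_breadth_mm = 10, voxel_mm = 1),
                    class = "crown_slice")
  expect_equal(dentine_percent(fake)$percent, 75)
  fake$volumes_mm3 <- c(dentine = 25, enamel = 25)
  expect_equal(dentine_percent(fake)$percent, 50)

  ph <- fx_tooth()
  sl <- fx_tooth_slice()
  dp <- dentine_percent(sl)
  zz <- (slice.index(ph$labels$data, 3) - 0.5) * ph$labels$voxel_mm
  inb <- zz > sl$section1$offset & zz < sl$section2$offset
  oracle <- 100 * sum(ph$labels$data == 1 & inb) /
    sum(ph$labels$data %in% 1:2 & inb)
  expect_lt(abs(dp$percent - oracle), 0.5)
})

test_that("dentine percent is invariant to 90-degree rotations and voxel rescaling", {
  ph <- fx_tooth()
  dp0 <- dentine_percent(extract_crown_slice(ph$labels,
                                             ph$truth$cervix_plane))
  dmm <- dim(ph$labels$data) * ph$labels$voxel_mm
  for (ax in c(1, 2)) {
    v <- rotate_volume(ph$labels, axis = ax, k = 1)
    p <- rotate_plane(ph$truth$cervix_plane, axis = ax, k = 1, dim_mm = dmm)
    dp <- dentine_percent(extract_crown_slice(v, p))
    expect_lt(abs(dp$percent - dp0$percent), 0.5)
  }
  # voxel-size rescaling: same grid, different physical scale
  v2 <- ph$labels; v2$voxel_mm <- 0.25
  p2 <- plane(c(0, 0, 1), ph$truth$z_cervix_mm * 2.5)
  dp2 <- dentine_percent(extract_crown_slice(v2, p2))
  expect_lt(abs(dp2$percent - dp0$percent), 0.5)
})

test_that("wear screening flags truncated cusps but not pristine teeth", {
  ph <- fx_tooth()
  wr0 <- detect_wear(fx_tooth_seg(), ph$truth$cervix_plane,
                     section2 = fx_tooth_slice()$section2)
  expect_false(wr0$worn)
  expect_gt(wr0$min_occlusal_enamel_frac, 0.5)

  phw <- gen_tooth_phantom(tooth_phantom_config(seed = 1,
                                                wear_truncation_frac = 0.2))
  wrw <- detect_wear(phw$labels, phw$truth$cervix_plane)
  expect_true(wrw$worn)

  # enamel cap fully removed occlusally
  phh <- gen_tooth_phantom(tooth_phantom_config(seed = 1,
                                                wear_truncation_frac = 0.55))
  wrh <- detect_wear(phh$labels, phh$truth$cervix_plane)
  expect_true(wrh$worn)
  expect_equal(wrh$severity, 1)
})

test_that("broken-cervix reconstruction recovers the unbroken dentine percent", {
  broken <- gen_tooth_phantom(tooth_phantom_config(seed = 1,
                                                   cervix_break_frac = 0.1))
  unbroken <- fx_tooth()
  refs <- list(
    gen_tooth_phantom(tooth_phantom_config(
      seed = 2, cusp_height_mm = c(2.4, 3.0)))$labels,
    gen_tooth_phantom(tooth_phantom_config(
      seed = 3, cusp_height_mm = c(2.8, 3.3),
      footprint_mm = c(2.5, 1.8)))$labels,
    gen_tooth_phantom(tooth_phantom_config(
      seed = 4, cusp_sigma_mm = c(0.75, 0.85)))$labels)
  truth <- dentine_percent(extract_crown_slice(unbroken$labels,
                                               unbroken$truth$cervix_plane))
  est <- reconstruct_broken_cervix(broken$labels, refs)
  vals <- vapply(est, `[[`, numeric(1), "percent")
  expect_length(vals, 3L)
  expect_lt(abs(mean(vals) - truth$percent), 2)

  # identity: unbroken target against itself
  est0 <- reconstruct_broken_cervix(unbroken$labels,
                                    rep(list(unbroken$labels), 3))
  for (e in est0) expect_lt(abs(e$percent - truth$percent), 0.5)

  expect_error(reconstruct_broken_cervix(broken$labels, refs[1:2]),
               "exactly 3")
  # disjoint/absent cervix
  empty <- label_volume(array(0L, c(8, 8, 8)), 0.1)
  expect_error(reconstruct_broken_cervix(empty, refs), "cervix")
})

test_that("BV/TV matches porosity on phantoms and calls maturity correctly", {
  solid <- gen_epiphysis_phantom(epiphysis_phantom_config(porosity = 0,
                                                          seed = 1))
  bv1 <- bv_tv(solid, attr(solid, "truth")$separation_plane)
  expect_equal(bv1$ratio, 1)
  expect_equal(bv1$maturity_call, "adult")

  por <- gen_epiphysis_phantom(epiphysis_phantom_config(porosity = 0.4,
                                                        seed = 2))
  bv2 <- bv_tv(por, attr(por, "truth")$separation_plane)
  expect_lt(abs(bv2$ratio - 0.60), 0.02)
  expect_equal(bv2$maturity_call, "immature")

  # plane with nothing proximal errors
  expect_error(bv_tv(solid, plane(c(0, 0, 1), 99)), "proximal")
})

test_that("BV/TV agrees with brute-force counting on a split half-space", {
  ep <- gen_epiphysis_phantom(epiphysis_phantom_config(porosity = 0,
                                                       seed = 3))
  ctr <- dim(ep$data) * ep$voxel_mm / 2
  pl <- plane(c(0, 0, 1), ctr[3])
  bv <- bv_tv(ep, pl)
  zz <- (slice.index(ep$data, 3) - 0.5) * ep$voxel_mm
  oracle_bv <- sum(ep$data == 1 & zz > ctr[3]) * ep$voxel_mm^3
  expect_equal(bv$BV, oracle_bv)
  expect_equal(bv$ratio, 1)
})

test_that("exact Mann-Whitney matches enumeration and handles ties", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)           # 2/20 rank splits as extreme
  expect_identical(r$method, "exact")
  # all values tied: p = 1 under exact tie handling
  expect_equal(compare_groups(rep(2, 5), rep(2, 7))$p_value, 1)
  # cross-check against the base-R exact distribution (tie-free case)
  set.seed(4)
  a <- rnorm(8); b <- rnorm(9) + 0.3
  ours <- compare_groups(a, b)
  ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$U, unname(ref$statistic))
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("fully separated samples of 21 and 23 are overwhelmingly significant", {
  a <- seq_len(21); b <- seq(100, 122)
  r <- compare_groups(a, b)          # n = 44: normal approximation path
  expect_identical(r$method, "normal")
  expect_lt(r$p_value, 1e-3)
})
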