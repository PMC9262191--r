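# Region features, GLCM/Haralick texture, second-channel features, sister
# distance and angular features.

test_that("a rasterized disk has the analytic area, near-1 circularity and unit axis ratio", {
  m <- disk_mask(64, 32, 32, 10)
  patch <- matrix(50, 64, 64)
  f <- compute_region_features(patch, m, pixel_size = 1)
  expect_equal(unname(f["area_px"]), 100 * pi, tolerance = 0.05)
  expect_gte(unname(f["circularity"]), 0.9)
  expect_lte(unname(f["circularity"]), 1.1)
  expect_equal(unname(f["major_axis"] / f["minor_axis"]), 1, tolerance = 0.05)
  expect_equal(unname(f["centroid_y"]), 32, tolerance = 0.01)
})

test_that("axis lengths and orientation match an independent moment computation", {
  m <- matrix(FALSE, 40, 40)
  m[19:22, 11:30] <- TRUE                  # 4 rows x 20 cols, along x
  f <- compute_region_features(matrix(1, 40, 40), m, 1)
  expect_equal(unname(f["orientation"]), 0, tolerance = 1e-8)
  # independent oracle: eigenvalues of the pixel covariance (+1/12)
  idx <- which(m, arr.ind = TRUE)
  cov2 <- cov(idx) * (nrow(idx) - 1) / nrow(idx) + diag(2) / 12
  ev <- sort(eigen(cov2)$values, decreasing = TRUE)
  expect_equal(unname(f["major_axis"]), 4 * sqrt(ev[1]), tolerance = 1e-6)
  expect_equal(unname(f["major_axis"] / f["minor_axis"]),
               sqrt(ev[1] / ev[2]), tolerance = 1e-6)
})

test_that("intensity statistics are exact for uniform masks and NA for empty masks", {
  m <- disk_mask(32, 16, 16, 6)
  f <- compute_region_features(matrix(100, 32, 32), m, 1)
  expect_equal(unname(f["mean_int"]), 100)
  expect_equal(unname(f["std_int"]), 0)
  fe <- compute_region_features(matrix(1, 8, 8), matrix(FALSE, 8, 8), 1)
  expect_true(all(is.na(fe)))
})

test_that("features are invariant under translation of patch and mask", {
  set.seed(5)
  patch <- matrix(runif(64^2, 0, 100), 64, 64)
  m <- disk_mask(64, 25, 25, 8)
  shift <- function(x, dy, dx) {
    out <- matrix(0, nrow(x), ncol(x))
    out[(1 + dy):nrow(x), (1 + dx):ncol(x)] <-
      x[1:(nrow(x) - dy), 1:(ncol(x) - dx)]
    out
  }
  f1 <- compute_region_features(patch, m, 1)
  f2 <- compute_region_features(shift(patch, 10, 7), shift(m, 10, 7) > 0, 1)
  keep <- setdiff(names(f1), c("centroid_y", "centroid_x"))
  expect_equal(f1[keep], f2[keep], tolerance = 1e-10)
})

test_that("GLCM counts match hand enumeration and respect the mask", {
  patch <- matrix(c(0, 0, 63, 63), 2, 2, byrow = TRUE)  # rows: (0,0),(63,63)
  g <- compute_glcm(patch, matrix(TRUE, 2, 2), levels = 64, offset = c(0, 1))
  expect_equal(g[1, 1], 1)                 # the (0,0) horizontal pair
  expect_equal(g[64, 64], 1)               # the (63,63) horizontal pair
  expect_equal(sum(g), 2)
  # constant patch: one diagonal entry only
  gc <- compute_glcm(matrix(5, 4, 4), matrix(TRUE, 4, 4), 64, c(0, 1))
  expect_equal(sum(gc), 12)
  expect_equal(sum(gc != 0), 1)
  expect_equal(gc[1, 1], 12)
  expect_error(compute_glcm(matrix(1:4, 2), matrix(FALSE, 2, 2), 64, c(0, 1)),
               "2 pixels")
})

test_that("masked GLCM equals exhaustive pair enumeration", {
  set.seed(11)
  patch <- matrix(sample(0:255, 100, TRUE), 10, 10)
  mask <- matrix(TRUE, 10, 10); mask[, 4] <- FALSE
  for (off in glcm_offsets()) {
    g <- compute_glcm(patch, mask, 64, off)
    # brute force: loop over every pixel pair
    rng <- range(patch)
    q <- pmin(floor((patch - rng[1]) / diff(rng) * 64), 63)
    expected <- matrix(0, 64, 64)
    for (r in 1:10) for (c in 1:10) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= 10 && c2 >= 1 && c2 <= 10 &&
          mask[r, c] && mask[r2, c2])
        expected[q[r, c] + 1, q[r2, c2] + 1] <-
          expected[q[r, c] + 1, q[r2, c2] + 1] + 1
    }
    expect_equal(unclass(g), expected, ignore_attr = TRUE)
  }
})

test_that("closed-form Haralick values hold for uniform and diagonal matrices", {
  u <- matrix(1, 64, 64)
  h <- haralick_features(list(structure(u, offset = c(0, 1))))
  expect_equal(unname(h["entropy"]), 12)               # log2(64^2) bits
  expect_equal(unname(h["asm"]), 64^-2)
  d <- diag(64)
  hd <- haralick_features(list(structure(d, offset = c(0, 1))))
  expect_equal(unname(hd["contrast"]), 0)
  expect_equal(unname(hd["idm"]), 1)
  # degenerate single-cell GLCM: correlation flagged missing, rest computed
  s <- matrix(0, 64, 64); s[3, 3] <- 5
  hs <- haralick_features(list(structure(s, offset = c(0, 1))))
  expect_true(is.na(hs["correlation"]))
  expect_equal(unname(hs["asm"]), 1)
})

test_that("Haralick averaging is invariant to offset order", {
  set.seed(3)
  patch <- matrix(runif(256, 0, 1000), 16, 16)
  mask <- disk_mask(16, 8, 8, 7)
  gl <- lapply(glcm_offsets(), function(o) compute_glcm(patch, mask, 64, o))
  expect_equal(haralick_features(gl), haralick_features(rev(gl)),
               tolerance = 1e-12)
})

test_that("second-channel features: identity at radius 0, displacement by construction, toroid counts", {
  mask <- disk_mask(96, 48, 48, 10)
  set.seed(2)
  p2 <- matrix(runif(96^2, 0, 50), 96, 96)
  f0 <- second_channel_features(p2, mask, radius = 0, region = "dilated")
  expect_equal(unname(f0["mean_int"]), mean(p2[mask]))
  expect_equal(unname(f0["max_int"]), max(p2[mask]))
  # one dominant pixel 10 px from the centroid
  p3 <- matrix(0, 96, 96); p3[48, 58] <- 99
  f1 <- second_channel_features(p3, mask, radius = 5, region = "dilated")
  expect_equal(unname(f1["max_int_displacement"]), 10, tolerance = 1e-8)
  # toroid area = dilated - eroded (erosion is a subset of dilation)
  brush <- EBImage::makeBrush(2 * 15 + 1, "disc")
  dil <- EBImage::dilate(mask * 1, brush) > 0
  ero <- EBImage::erode(mask * 1, brush) > 0
  ft <- second_channel_features(p2 + 1, mask, radius = 15, region = "toroid")
  expect_equal(unname(ft["mean_int"]), mean((p2 + 1)[dil & !ero]))
  expect_equal(sum(dil & !ero), sum(dil) - sum(ero))
  # fully eroded-away mask flags missing
  fe <- second_channel_features(p2, disk_mask(96, 48, 48, 3), radius = 15,
                                region = "eroded")
  expect_true(all(is.na(fe)))
})

test_that("sister distance: 3-4-5 triangle, pixel-size scaling, zero before division", {
  traj <- function(y, x, div) {
    d <- data.frame(frame = seq_along(y), y = y, x = x)
    attr(d, "division_frame") <- div
    d
  }
  a <- traj(c(5, 5, 0), c(5, 5, 0), 2)
  b <- traj(c(5, 8, 3), c(5, 9, 4), 2)
  expect_equal(sister_distance(a, b, 1), c(0, 5, 5))
  expect_equal(sister_distance(a, b, 0.5), c(0, 2.5, 2.5))
})

test_that("sister distance on the synthetic fixture follows the generator's linear ramp", {
  gm <- small_sim()
  tf <- gm$truth$frames
  kids <- gm$truth$cells[!is.na(gm$truth$cells$parent_id), ]
  pr <- kids$parent_id[1]
  pair <- kids[kids$parent_id == pr, ]
  f0 <- pair$first_frame[1]
  frames <- f0:(f0 + 9)
  d <- vapply(frames, function(t) {
    z <- tf[tf$frame == t & tf$cell_id %in% pair$cell_id, ]
    sqrt(diff(z$y)^2 + diff(z$x)^2)
  }, 0)
  p <- gm$truth$params
  expect_equal(diff(d), rep(2 * p$anaphase_speed, 9), tolerance = 1e-10)
})

test_that("angular features wrap axial angles and sum rotations", {
  expect_equal(unname(angular_features(rep(10, 20), 5, 15, 10)),
               c(0, 0))
  theta <- 5 * (0:19)                      # 5 degrees per frame
  f <- angular_features(theta, 1, 11, 0)
  expect_equal(unname(f["sum_abs_angular_change"]), 50)
  # wrap-around: 88 -> -88 is a 4-degree axial step, not 176
  f2 <- angular_features(c(80, 88, -88, -80), 1, 4, 90)
  expect_equal(unname(f2["sum_abs_angular_change"]), 8 + 4 + 8)
  expect_true(is.na(angular_features(1:5, 2, 3, 0)["sum_abs_angular_change"]))
})
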