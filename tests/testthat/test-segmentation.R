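# Otsu threshold, classical patch segmentation, instance-label merge.

# Independent Otsu oracle: literal scan over all 255 bin boundaries,
# recomputing class weights and means from the histogram each time.
otsu_bruteforce <- function(patch) {
  v <- as.numeric(patch)
  rng <- range(v)
  bin <- pmin(floor((v - rng[1]) / diff(rng) * 256), 255)
  h <- tabulate(bin + 1L, 256)
  mids <- rng[1] + (0:255 + 0.5) / 256 * diff(rng)
  best <- -Inf; bestk <- NA
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):256])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best + 1e-9) { best <- bc; bestk <- k }
  }
  rng[1] + bestk / 256 * diff(rng)
}

test_that("Otsu separates a two-level image between the modes", {
  patch <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  th <- otsu_threshold(patch)
  expect_gt(th, 10); expect_lt(th, 200)
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  set.seed(42)
  for (i in 1:25) {
    patch <- matrix(c(rnorm(60, 50, 12), rnorm(40, 160, 20)), 10, 10)
    expect_equal(otsu_threshold(patch), otsu_bruteforce(patch),
                 tolerance = 1e-12)
  }
})

test_that("Otsu is shift-equivariant up to one bin width and errors on constants", {
  set.seed(1)
  patch <- matrix(c(runif(50, 0, 60), runif(50, 150, 255)), 10, 10)
  binw <- diff(range(patch)) / 256
  expect_equal(otsu_threshold(patch + 30), otsu_threshold(patch) + 30,
               tolerance = binw + 1e-9)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

# Render a soft-edged disk the way the generator does.
soft_disk <- function(size, cy, cx, r, amp, bg = 10) {
  X <- matrix(seq_len(size), size, size, byrow = TRUE)
  Y <- t(X)
  rho2 <- ((Y - cy)^2 + (X - cx)^2) / r^2
  bg + amp * exp(-rho2^3)
}

test_that("a centred bright disk is segmented with Dice >= 0.9 against the analytic disk", {
  patch <- soft_disk(96, 48, 48, 15, 150)
  seg <- segment_patch_classical(patch)
  expect_false(seg$failed)
  truth <- disk_mask(96, 48, 48, 15)
  dice <- 2 * sum(seg$mask & truth) / (sum(seg$mask) + sum(truth))
  expect_gte(dice, 0.9)
})

test_that("a dim central cell next to a brighter neighbour is retained", {
  patch <- soft_disk(96, 48, 48, 12, 60) + soft_disk(96, 48, 18, 12, 150) - 10
  seg <- segment_patch_classical(patch)
  expect_false(seg$failed)
  expect_gt(sum(seg$mask), 100)
  # the retained mask is the central cell, not the bright neighbour
  idx <- which(seg$mask, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 2]) - 48), 5)
})

test_that("the neighbouring cell is claimed by the border seed across the background gap", {
  # the border seed reaches separated neighbours through the background, so
  # only the central cell survives (touching cells are the instance-merge
  # path's job)
  patch <- soft_disk(96, 48, 48, 13, 120) + soft_disk(96, 48, 80, 13, 120) - 10
  seg <- segment_patch_classical(patch)
  expect_false(seg$failed)
  idx <- which(seg$mask, arr.ind = TRUE)
  expect_lt(max(idx[, 2]), 66)             # does not extend into the neighbour
})

test_that("a blank patch yields an empty mask with the failure flag", {
  seg <- segment_patch_classical(matrix(12, 96, 96))
  expect_true(seg$failed)
  expect_false(any(seg$mask))
})

test_that("the mask is invariant under global intensity scaling", {
  patch <- soft_disk(96, 46, 50, 14, 130)
  m1 <- segment_patch_classical(patch)$mask
  m2 <- segment_patch_classical(patch * 3.7)$mask
  m3 <- segment_patch_classical(patch * 0.2)$mask
  expect_identical(m1, m2)
  expect_identical(m1, m3)
})

test_that("masks are single 4-connected components containing the centre", {
  set.seed(8)
  for (i in 1:5) {
    patch <- soft_disk(96, 48 + runif(1, -3, 3), 48 + runif(1, -3, 3),
                       runif(1, 8, 16), runif(1, 80, 200)) +
      matrix(rnorm(96^2, 0, 5), 96, 96)
    seg <- segment_patch_classical(patch)
    if (seg$failed) next
    lab <- EBImage::bwlabel(seg$mask * 1)
    expect_equal(max(lab), 1)
    expect_true(seg$mask[48, 48])
  }
})

test_that("instance-label merge keeps the central instance and falls back when absent", {
  lab <- matrix(0L, 200, 200)
  lab[disk_mask(200, 100, 100, 12)] <- 5L
  lab[disk_mask(200, 100, 140, 12)] <- 9L
  img <- soft_disk(200, 100, 100, 12, 120) + soft_disk(200, 100, 140, 12, 120) - 10
  res <- merge_instance_segmentation(lab, data.frame(y = 100, x = 100),
                                     patch_size = 96, intensity_image = img)
  expect_false(res[[1]]$fallback)
  expect_equal(sum(res[[1]]$mask), sum(lab == 5L))   # neighbour excluded
  # no instance near this detection: classical fallback, flagged
  res2 <- merge_instance_segmentation(lab, data.frame(y = 40, x = 40),
                                      patch_size = 96, intensity_image = img)
  expect_true(res2[[1]]$fallback)
  # dimension mismatch rejected
  expect_error(merge_instance_segmentation(lab[1:100, ],
                                           data.frame(y = 10, x = 10),
                                           96, intensity_image = img),
               "dimensions")
})

test_that("combined external labels + fallback yield non-empty masks for nearly all detections", {
  gm <- small_sim()
  dets <- small_detections()
  n_total <- 0L; n_ok <- 0L
  for (t in seq(1, gm$movie$frame_count, by = 10)) {
    res <- merge_instance_segmentation(gm$truth$labels[, , t], dets[[t]],
                                       patch_size = 96,
                                       intensity_image = gm$movie$channels[[1]][, , t])
    n_total <- n_total + length(res)
    n_ok <- n_ok + sum(vapply(res, function(r) any(r$mask), TRUE))
  }
  expect_gte(n_ok / n_total, 0.99)
})
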