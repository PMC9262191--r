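# Synthetic mitotic-movie generator: geometry, dynamics, ground truth.

static_params <- function(n_frames = 5) {
  sim_params(image_size = c(96, 96), n_cells = 1, division_schedule = NULL,
             n_frames = n_frames, noise_sd = 0, motion_sd = 0, margin = 40,
             min_spacing = 2, second_channel = FALSE, seed = 3)
}

test_that("a non-dividing noiseless cell is static: identical frames, constant centroid", {
  gm <- generate_movie(static_params())
  ch <- gm$movie$channels[[1]]
  for (t in 2:5) expect_identical(ch[, , t], ch[, , 1])
  tf <- gm$truth$frames
  expect_equal(length(unique(tf$y)), 1L)
  expect_equal(length(unique(tf$x)), 1L)
  expect_true(all(tf$state == 1L))
})

test_that("a fixed seed reproduces bit-identical pixels and ground truth", {
  p <- sim_params(image_size = c(200, 200), n_cells = 2,
                  division_schedule = data.frame(cell_id = 1L,
                                                 division_frame = 35L),
                  n_frames = 95, margin = 50, min_spacing = 60, seed = 11)
  a <- generate_movie(p)
  b <- generate_movie(p)
  expect_identical(a$movie$channels, b$movie$channels)
  expect_identical(a$truth$frames, b$truth$frames)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("division populates two daughters whose separation follows the pole equations", {
  p <- sim_params(image_size = c(300, 300), n_cells = 1,
                  division_schedule = data.frame(cell_id = 1L,
                                                 division_frame = 41L),
                  n_frames = 100, margin = 90, min_spacing = 2,
                  noise_sd = 0, motion_sd = 0, second_channel = FALSE,
                  seed = 5)
  gm <- generate_movie(p)
  counts <- table(gm$truth$frames$frame)
  expect_true(all(counts[1:40] == 1))
  expect_true(all(counts[41:100] == 2))
  tf <- gm$truth$frames
  d <- vapply(41:100, function(t) {
    z <- tf[tf$frame == t, ]
    sqrt(diff(z$y)^2 + diff(z$x)^2)
  }, 0)
  expect_true(all(diff(d) > 0))            # strictly increasing separation
  # generator's own pole-trajectory equation
  dt <- (41:100) - 41
  expected <- p$initial_separation + 2 * p$anaphase_speed *
    pmin(dt, p$separation_duration) +
    0.1 * pmax(0, dt - p$separation_duration)
  expect_equal(d, expected, tolerance = 1e-10)
})

test_that("noiseless masks match analytic ellipse area and configured intensity gain", {
  p <- sim_params(image_size = c(220, 220), n_cells = 1,
                  division_schedule = data.frame(cell_id = 1L,
                                                 division_frame = 45L),
                  n_frames = 110, margin = 70, min_spacing = 2,
                  noise_sd = 0, motion_sd = 0, second_channel = FALSE,
                  seed = 9)
  gm <- generate_movie(p)
  a0 <- p$interphase_radius * 1.1
  b0 <- p$interphase_radius / 1.1
  area1 <- sum(gm$truth$labels[, , 1] == 1L)
  expect_equal(area1, pi * a0 * b0, tolerance = 0.05)
  img1 <- gm$movie$channels[[1]][, , 1]
  mean_interphase <- mean(img1[gm$truth$labels[, , 1] == 1L])
  for (t in c(34, 40)) {                   # condensed blob and metaphase plate
    st <- gm$truth$frames$state[gm$truth$frames$frame == t]
    expect_equal(st, 2L)
    img <- gm$movie$channels[[1]][, , t]
    mean_mito <- mean(img[gm$truth$labels[, , t] == 1L])
    expect_equal(mean_mito / mean_interphase, p$intensity_gain,
                 tolerance = 0.1)
  }
})

test_that("ground-truth states are monotone 1->2->3 with both anchors, shared by siblings", {
  gm <- small_sim()
  cells <- gm$truth$cells
  mothers <- cells[!is.na(cells$division_frame), ]
  for (i in seq_len(nrow(mothers))) {
    kids <- cells[!is.na(cells$parent_id) &
                  cells$parent_id == mothers$cell_id[i], ]
    expect_equal(nrow(kids), 2L)
    expect_equal(kids$ip_frame[1], kids$ip_frame[2])
    expect_equal(kids$ma_frame[1], kids$ma_frame[2])
    for (k in seq_len(2)) {
      states <- c(
        gm$truth$frames$state[gm$truth$frames$cell_id == mothers$cell_id[i]],
        gm$truth$frames$state[gm$truth$frames$cell_id == kids$cell_id[k]])
      expect_true(all(diff(states) >= 0))
      expect_setequal(unique(states), 1:3)
    }
  }
})

test_that("overlapping cell configurations are rejected", {
  p <- sim_params(image_size = c(64, 64), n_cells = 2,
                  division_schedule = NULL, n_frames = 2, margin = 20,
                  min_spacing = 2, second_channel = FALSE, seed = 3)
  expect_error(generate_movie(p), "overlap")
})

test_that("schedules violating the trajectory window are rejected", {
  expect_error(sim_params(division_schedule = data.frame(
    cell_id = 1L, division_frame = 10L)), "window|trajector")
  expect_error(sim_params(division_schedule = data.frame(
    cell_id = 1L, division_frame = 115L)), "window|trajector")
  expect_error(sim_params(prophase_shrink = 1.2), "prophase_shrink")
  expect_error(sim_params(noise_sd = -1), "noise_sd")
})

test_that("write_fixture writes ordered per-frame TIFFs that round-trip, and complete truth tables", {
  p <- static_params(n_frames = 10)
  gm <- generate_movie(p)
  dir <- withr::local_tempdir()
  write_fixture(gm$movie, gm$truth, dir)
  tifs <- list.files(dir, pattern = "^chromatin_.*\\.tif$")
  expect_length(tifs, 10L)
  expect_identical(tifs, sort(tifs))       # lexicographic == temporal
  for (t in c(1L, 10L)) {
    img <- tiff::readTIFF(file.path(dir, sprintf("chromatin_t%04d.tif", t)),
                          as.is = TRUE)
    expect_equal(unclass(img) * 1.0, gm$movie$channels[[1]][, , t])
  }
  tf <- read.csv(file.path(dir, "truth_frames.csv"))
  expect_equal(nrow(tf), sum(vapply(seq_len(10), function(t)
    sum(gm$truth$frames$frame == t), 0L)))
})
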