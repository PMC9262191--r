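# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Small two-division movie + ground truth (noisy, two channels).
small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    p <- sim_params(image_size = c(360, 360), n_cells = 6,
                    division_schedule = data.frame(
                      cell_id = 1:2, division_frame = c(40L, 50L)),
                    n_frames = 110, second_channel = TRUE, seed = 7)
    .fixture_cache$sim <- generate_movie(p)
  }
  .fixture_cache$sim
}

# Per-frame detections on the small movie (detection is the slow step).
small_detections <- function() {
  if (is.null(.fixture_cache$dets))
    .fixture_cache$dets <- detect_movie(small_sim()$movie)
  .fixture_cache$dets
}

# Full pipeline output on the small movie.
small_project <- function() {
  if (is.null(.fixture_cache$proj)) {
    gm <- small_sim()
    .fixture_cache$proj <- run_pipeline(gm$movie)
  }
  .fixture_cache$proj
}

# Hand-built toy project: deterministic values, no imaging involved.
# Cells alternate between two treatments; features "f1" rises at IP by
# `gain`, "f2" stays constant.
toy_project <- function(n_cells = 6, n_frames = 30, ip = 10, ma = 20,
                        gain = 2, treatments = c("ctrl", "drug")) {
  ip <- max(2L, min(ip, n_frames - 1L))
  ma <- max(ip + 1L, min(ma, n_frames))
  cells <- lapply(seq_len(n_cells), function(i) {
    s <- sync_states(n_frames, ip = ip, ma = ma)
    f1 <- rep(10, n_frames)
    f1[s$states >= 2L] <- 10 * gain
    f2 <- rep(5, n_frames)
    ts <- cbind(f1 = f1 + (i - 1) * 0.01, f2 = f2)
    list(id = sprintf("c%02d", i), pair = ceiling(i / 2),
         daughter = c("a", "b")[1 + (i - 1) %% 2],
         sibling = NA, division_frame = ma, frames = seq_len(n_frames),
         centroids = cbind(y = rep(i, n_frames), x = seq_len(n_frames)),
         ts = ts,
         single = c(score = as.numeric(i),
                    interphase_f1 = mean(f1[seq_len(ip - 1)])),
         sync = s,
         metadata = c(microscope = "m1",
                      experiment_id = sprintf("e%d", 1 + (i > n_cells / 2)),
                      treatment = treatments[1 + (i - 1) %% 2]))
  })
  cell_project(cells, config = list(toy = TRUE))
}

# Rasterized disk mask/patch builders used by several suites.
disk_mask <- function(size, cy, cx, r) {
  idx <- expand.grid(y = seq_len(size), x = seq_len(size))
  m <- matrix((idx$y - cy)^2 + (idx$x - cx)^2 <= r^2, size, size)
  m
}
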