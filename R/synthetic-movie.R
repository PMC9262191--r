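#' Parameters for the synthetic mitotic-movie generator
#'
#' The generator emulates the chromatin dynamics of cultured human cells
#' (HeLa-like) passing through mitosis at the acquisition settings of typical
#' widefield/confocal screens: 3-minute sampling, 0.65 um/px, nuclei of about
#' 12 um diameter that hardly move between frames. Each dividing cell follows
#' interphase -> chromatin condensation (area shrinks by `prophase_shrink^2`,
#' mask mean intensity rises by `intensity_gain`) -> an elongated, optionally
#' rotating metaphase plate -> two sister chromatin masses separating linearly
#' along a random division axis -> telophase decondensation back towards
#' interphase statistics. Cells are rendered as smooth super-Gaussian
#' elliptical profiles (not binary disks) so thresholding and watershed are
#' non-trivially exercised; an optional second channel renders a spindle-like
#' signal between the poles during mitosis.
#'
#' Defaults define the package's reference fixture: 20 cells, 5 divisions,
#' 120 frames.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param n_frames number of frames.
#' @param sampling_interval minutes per frame.
#' @param pixel_size micrometres per pixel.
#' @param n_cells number of (mother) cells at frame 1.
#' @param division_schedule data.frame with columns `cell_id`,
#'   `division_frame` (1-based; the division frame is the first frame at which
#'   the two daughters exist, i.e. early anaphase). Must leave room for the
#'   default trajectory window: `window_before < division_frame` and
#'   `division_frame + window_after - 1 <= n_frames`.
#' @param window_before,window_after the trajectory window the schedule must
#'   respect (defaults 30 and 60 frames).
#' @param interphase_radius nominal interphase nucleus radius in pixels.
#' @param prophase_shrink linear shrink factor of the condensed chromatin
#'   (area shrinks by its square), in (0, 1).
#' @param intensity_gain factor (> 1) by which the mask mean intensity rises
#'   during condensation, measured on the rendered image including background.
#' @param anaphase_speed pole speed in px/frame; the sister-centroid distance
#'   grows at twice this rate during the separation phase.
#' @param initial_separation sister-centroid distance (px) at the division
#'   frame.
#' @param separation_duration frames of fast anaphase separation; afterwards
#'   the distance keeps growing slowly (0.1 px/frame) so it is strictly
#'   monotone.
#' @param condensation_lead frames between the IP transition and the division
#'   frame (prophase..metaphase duration).
#' @param telophase_duration frames over which daughters decondense back to
#'   interphase geometry and intensity.
#' @param metaphase_elongation axis elongation factor of the metaphase plate.
#' @param rotation_amplitude amplitude (degrees) of the metaphase-plate
#'   orientation oscillation; 0 disables rotation.
#' @param rotation_period oscillation period in frames.
#' @param motion_sd per-frame random-walk step (px) of cell centres.
#' @param interphase_amplitude peak intensity of an interphase nucleus above
#'   background (a.u., 16-bit scale).
#' @param background_level background intensity.
#' @param noise_sd Gaussian read-noise standard deviation (0 = noiseless).
#' @param second_channel render the spindle-like second channel?
#' @param min_spacing minimum distance between (non-sibling) cell centres.
#' @param margin minimum distance of cell centres to the image border.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(image_size = c(560, 560), n_frames = 120,
                       sampling_interval = 3, pixel_size = 0.65,
                       n_cells = 20,
                       division_schedule = data.frame(
                         cell_id = 1:5,
                         division_frame = c(40L, 44L, 48L, 52L, 56L)),
                       window_before = 30, window_after = 60,
                       interphase_radius = 9,
                       prophase_shrink = 0.6,
                       intensity_gain = 1.8,
                       anaphase_speed = 2,
                       initial_separation = 11,
                       separation_duration = 10,
                       condensation_lead = 12,
                       telophase_duration = 15,
                       metaphase_elongation = 1.3,
                       rotation_amplitude = 15,
                       rotation_period = 12,
                       motion_sd = 0.5,
                       interphase_amplitude = 120,
                       background_level = 10,
                       noise_sd = 8,
                       second_channel = TRUE,
                       min_spacing = 90,
                       margin = 80,
                       seed = 1L) {
  p <- as.list(environment())
  if (length(p$image_size) != 2L || any(p$image_size < 64))
    stop_mitotraj("'image_size' must be c(H, W) with H, W >= 64")
  if (p$n_frames < 1) stop_mitotraj("'n_frames' must be >= 1")
  if (p$interphase_radius <= 0) stop_mitotraj("'interphase_radius' must be > 0")
  if (p$prophase_shrink <= 0 || p$prophase_shrink >= 1)
    stop_mitotraj("'prophase_shrink' must be in (0, 1)")
  if (p$intensity_gain <= 1) stop_mitotraj("'intensity_gain' must be > 1")
  if (p$noise_sd < 0) stop_mitotraj("'noise_sd' must be >= 0")
  ds <- p$division_schedule
  if (!is.null(ds) && nrow(ds)) {
    stopifnot(all(c("cell_id", "division_frame") %in% names(ds)))
    if (any(ds$cell_id < 1 | ds$cell_id > p$n_cells))
      stop_mitotraj("division_schedule cell_id out of 1..n_cells")
    if (anyDuplicated(ds$cell_id))
      stop_mitotraj("a cell can divide at most once")
    bad <- ds$division_frame <= p$window_before |
      ds$division_frame + p$window_after - 1 > p$n_frames |
      ds$division_frame - p$condensation_lead < 2
    if (any(bad))
      stop_mitotraj("division_frame must lie in [",
                    max(p$window_before + 1, p$condensation_lead + 2), ", ",
                    p$n_frames - p$window_after + 1,
                    "] so extracted trajectories satisfy the default window")
  }
  class(p) <- "sim_params"
  p
}

# mean of the radial profile exp(-rho^6) over the unit disk, i.e. the
# integral of exp(-s^3) over [0, 1]; relates peak amplitude to mask mean.
.profile_mean <- 0.80751118213967143511

# Per-frame geometric/intensity description of every live cell.
# Returns a data.frame with one row per (frame, cell).
.simulate_timeline <- function(p) {
  H <- p$image_size[1]; W <- p$image_size[2]
  a0 <- p$interphase_radius * 1.1
  b0 <- p$interphase_radius / 1.1
  A1 <- p$interphase_amplitude
  bg <- p$background_level
  cmu <- .profile_mean
  A2 <- ((cmu * A1 + bg) * p$intensity_gain - bg) / cmu  # exact mask-mean gain

  div <- p$division_schedule
  if (is.null(div)) div <- data.frame(cell_id = integer(), division_frame = integer())

  # seeded placement on a jittered grid: pitch = min_spacing + 2*jitter
  # guarantees the spacing while keeping positions random, like a
  # semi-confluent culture
  jit <- 5
  pitch <- p$min_spacing + 2 * jit
  ys <- seq(p$margin, H - p$margin, by = pitch)
  xs <- seq(p$margin, W - p$margin, by = pitch)
  sites <- as.matrix(expand.grid(y = ys, x = xs))
  if (nrow(sites) < p$n_cells)
    stop_mitotraj("could not place ", p$n_cells, " cells with min_spacing ",
                  p$min_spacing, " in a ", H, "x", W, " image")
  sel <- sample.int(nrow(sites), p$n_cells)
  centers <- sites[sel, , drop = FALSE] +
    matrix(runif(2 * p$n_cells, -jit, jit), ncol = 2)
  phi0 <- runif(p$n_cells, -90, 90)        # interphase orientation
  axis_angle <- runif(p$n_cells, -90, 90)  # division axis (axial, degrees)

  # random walks of the lineage centres (mother continued by the sister pair)
  walks <- lapply(seq_len(p$n_cells), function(i) {
    steps <- matrix(rnorm(2 * p$n_frames, 0, p$motion_sd), ncol = 2)
    steps[1, ] <- 0
    sweep(apply(steps, 2, cumsum), 2, centers[i, ], "+")
  })

  cells <- data.frame(cell_id = seq_len(p$n_cells),
                      parent_id = NA_integer_,
                      daughter = NA_character_,
                      first_frame = 1L, last_frame = p$n_frames,
                      division_frame = NA_integer_,
                      ip_frame = NA_integer_, ma_frame = NA_integer_,
                      axis_angle = axis_angle,
                      stringsAsFactors = FALSE)
  next_id <- p$n_cells + 1L
  daughters <- list()
  for (r in seq_len(nrow(div))) {
    m <- div$cell_id[r]; f <- div$division_frame[r]
    cells$last_frame[m] <- f - 1L
    cells$division_frame[m] <- f
    cells$ip_frame[m] <- f - p$condensation_lead
    cells$ma_frame[m] <- f
    for (d in c("a", "b")) {
      daughters[[length(daughters) + 1L]] <-
        data.frame(cell_id = next_id, parent_id = m, daughter = d,
                   first_frame = f, last_frame = p$n_frames,
                   division_frame = NA_integer_,
                   ip_frame = f - p$condensation_lead, ma_frame = f,
                   axis_angle = axis_angle[m], stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
  }
  cells <- rbind(cells, do.call(rbind, daughters))

  plate_delay <- 3L  # condensed-blob frames before the plate elongates
  rows <- vector("list", nrow(cells) * 4L)
  ri <- 0L
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    lineage <- if (is.na(ci$parent_id)) ci$cell_id else ci$parent_id
    walk <- walks[[lineage]]
    for (t in seq(ci$first_frame, ci$last_frame)) {
      pos <- walk[t, ]
      if (is.na(ci$parent_id)) {           # mother (or non-dividing cell)
        if (is.na(ci$ip_frame) || t < ci$ip_frame) {
          st <- 1L; a <- a0; b <- b0; th <- phi0[ci$cell_id]; A <- A1
        } else {                           # state 2: condensed then plate
          st <- 2L
          if (t < ci$ip_frame + plate_delay) {
            a <- a0 * p$prophase_shrink; b <- b0 * p$prophase_shrink
            th <- phi0[ci$cell_id]
          } else {
            a <- a0 * p$prophase_shrink * p$metaphase_elongation
            b <- b0 * p$prophase_shrink / p$metaphase_elongation
            th <- ci$axis_angle + 90 +
              p$rotation_amplitude * sin(2 * pi * (t - ci$ip_frame - plate_delay) /
                                         p$rotation_period)
          }
          A <- A2
        }
      } else {                             # daughter: state 3 decondensation
        st <- 3L
        dt <- t - ci$first_frame
        dist <- p$initial_separation + 2 * p$anaphase_speed *
          min(dt, p$separation_duration) + 0.1 * max(0, dt - p$separation_duration)
        ang <- ci$axis_angle * pi / 180
        u <- c(-sin(ang), cos(ang))        # (row, col) unit vector of the axis
        sgn <- if (ci$daughter == "a") 1 else -1
        pos <- pos + sgn * (dist / 2) * u
        f <- clamp(dt / p$telophase_duration, 0, 1)
        a <- (1 - f) * (a0 * p$prophase_shrink * 0.75) + f * (0.92 * a0)
        b <- (1 - f) * (b0 * p$prophase_shrink * 0.75) + f * (0.92 * b0)
        A <- (1 - f) * A2 + f * A1
        th <- ci$axis_angle + 90
      }
      ri <- ri + 1L
      rows[[ri]] <- c(t, ci$cell_id, pos[1], pos[2], a, b,
                      wrap_axial(th), A, st)
    }
  }
  tl <- as.data.frame(do.call(rbind, rows[seq_len(ri)]))
  names(tl) <- c("frame", "cell_id", "y", "x", "a", "b",
                 "orientation", "amplitude", "state")
  tl$frame <- as.integer(tl$frame); tl$cell_id <- as.integer(tl$cell_id)
  tl$state <- as.integer(tl$state)
  list(timeline = tl[order(tl$frame, tl$cell_id), ], cells = cells)
}

# Rasterize one cell into the frame canvas and label image (in place via
# environment would be awkward; return the modified pair).
.render_cell <- function(canvas, labels, y, x, a, b, theta_deg, A, id,
                         siblings) {
  H <- nrow(canvas); W <- ncol(canvas)
  ext <- ceiling(2.2 * max(a, b))
  r0 <- max(1L, floor(y - ext)); r1 <- min(H, ceiling(y + ext))
  c0 <- max(1L, floor(x - ext)); c1 <- min(W, ceiling(x + ext))
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - y
  dx <- cc - x
  th <- theta_deg * pi / 180
  # axis unit vector in (row, col) coords for a math-convention angle
  # (counterclockwise from +x with y up): (row, col) = (-sin, cos)
  DY <- matrix(dy, length(rr), length(cc))
  DX <- matrix(dx, length(rr), length(cc), byrow = TRUE)
  u <- DX * cos(th) - DY * sin(th)
  v <- DX * sin(th) + DY * cos(th)
  rho2 <- (u / a)^2 + (v / b)^2
  canvas[rr, cc] <- canvas[rr, cc] + A * exp(-rho2^3)
  inside <- rho2 <= 1
  if (any(inside)) {
    sub <- labels[rr, cc]
    clash <- inside & sub != 0L & !(sub %in% c(id, siblings))
    if (any(clash))
      stop_mitotraj("overlapping masks of cells ", id, " and ",
                    paste(unique(sub[clash]), collapse = ","),
                    " - invalid configuration")
    sub[inside] <- id
    labels[rr, cc] <- sub
  }
  list(canvas = canvas, labels = labels)
}

#' Generate a synthetic mitotic movie with ground truth
#'
#' Renders the timeline described by [sim_params()] into a one- or two-channel
#' [movie_stack()] and returns complete ground truth: per-frame centroids,
#' states and label masks per cell, and per-cell event frames (division, IP
#' and MA anchors, lineage). Output is deterministic for a fixed seed.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `movie` (a [movie_stack()]) and `truth`
#'   (list: `cells` data.frame, `frames` data.frame, `labels` H x W x T
#'   integer array, `params`).
#' @export
generate_movie <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  sim <- .simulate_timeline(p)
  tl <- sim$timeline
  H <- p$image_size[1]; W <- p$image_size[2]; TT <- p$n_frames
  chrom <- array(0, dim = c(H, W, TT))
  labels <- array(0L, dim = c(H, W, TT))
  spind <- if (p$second_channel) array(0, dim = c(H, W, TT)) else NULL

  sib <- function(id) {
    row <- sim$cells[sim$cells$cell_id == id, ]
    if (is.na(row$parent_id)) return(integer())
    sim$cells$cell_id[!is.na(sim$cells$parent_id) &
                      sim$cells$parent_id == row$parent_id &
                      sim$cells$cell_id != id]
  }

  for (t in seq_len(TT)) {
    canvas <- matrix(0, H, W)
    lab <- matrix(0L, H, W)
    sub <- tl[tl$frame == t, ]
    for (k in seq_len(nrow(sub))) {
      res <- .render_cell(canvas, lab, sub$y[k], sub$x[k], sub$a[k], sub$b[k],
                          sub$orientation[k], sub$amplitude[k],
                          sub$cell_id[k], sib(sub$cell_id[k]))
      canvas <- res$canvas; lab <- res$labels
    }
    if (!is.null(spind)) {
      sp <- matrix(0, H, W)
      # spindle: elongated profile between the (virtual) poles during mitosis
      mito <- sub[sub$state >= 2L, ]
      done <- character()
      for (k in seq_len(nrow(mito))) {
        key <- as.character(if (!is.na(mito$cell_id[k]) &&
                                mito$state[k] == 3L) {
          prt <- sim$cells$parent_id[sim$cells$cell_id == mito$cell_id[k]]
          prt
        } else mito$cell_id[k])
        if (key %in% done) next
        done <- c(done, key)
        if (mito$state[k] == 2L) {
          cy <- mito$y[k]; cx <- mito$x[k]
          ci <- sim$cells[sim$cells$cell_id == mito$cell_id[k], ]
          half <- 8; amp <- 60
          axisang <- ci$axis_angle
        } else {
          pr <- sim$cells$parent_id[sim$cells$cell_id == mito$cell_id[k]]
          pair <- sub[sub$cell_id %in% sim$cells$cell_id[
            !is.na(sim$cells$parent_id) & sim$cells$parent_id == pr], ]
          cy <- mean(pair$y); cx <- mean(pair$x)
          half <- sqrt(diff(pair$y)^2 + diff(pair$x)^2) / 2 + 4
          dt <- t - sim$cells$first_frame[sim$cells$cell_id == mito$cell_id[k]]
          amp <- 60 * max(0, 1 - dt / (p$separation_duration + 5))
          axisang <- sim$cells$axis_angle[sim$cells$cell_id == mito$cell_id[k]]
        }
        if (amp <= 0) next
        res <- .render_cell(sp, matrix(0L, H, W), cy, cx, half, 5,
                            axisang, amp, 1L, integer())
        sp <- res$canvas
      }
      if (p$noise_sd > 0) sp <- sp + rnorm(H * W, 0, p$noise_sd)
      spind[, , t] <- clamp(round(sp + p$background_level), 0, 65535)
    }
    if (p$noise_sd > 0) canvas <- canvas + rnorm(H * W, 0, p$noise_sd)
    chrom[, , t] <- clamp(round(canvas + p$background_level), 0, 65535)
    labels[, , t] <- lab
  }

  channels <- list(chromatin = chrom)
  if (!is.null(spind)) channels$second <- spind
  movie <- movie_stack(channels, pixel_size = p$pixel_size,
                       sampling_interval = p$sampling_interval,
                       metadata = c(microscope = "synthetic",
                                    experiment_id = "sim",
                                    plate = "1", position = "1",
                                    treatment = "none"))
  truth <- list(cells = sim$cells,
                frames = tl[, c("frame", "cell_id", "y", "x", "orientation",
                                "state")],
                labels = labels,
                params = p)
  list(movie = movie, truth = truth)
}

#' Write a movie and its ground truth to a directory of plain files
#'
#' One 16-bit grayscale TIFF per frame per channel, named
#' `<channel>_t%04d.tif` so that lexicographic order equals temporal order;
#' ground-truth label images as `labels_t%04d.tif`; ground truth tables as
#' CSV (`truth_frames.csv`: one row per cell-frame with columns
#' frame, cell_id, y, x, orientation, state; `truth_cells.csv`: one row per
#' cell with lineage and event frames).
#'
#' @param movie a [movie_stack()].
#' @param truth the ground-truth list from [generate_movie()] (optional).
#' @param dir output directory (created if missing).
#' @param labels write ground-truth label TIFFs as well?
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(movie, truth = NULL, dir, labels = !is.null(truth)) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop_mitotraj("cannot create directory ", dir)
  }
  written <- character()
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    for (t in seq_len(dim(arr)[3])) {
      f <- file.path(dir, sprintf("%s_t%04d.tif", ch, t))
      ok <- try(tiff::writeTIFF(arr[, , t] / 65535, f, bits.per.sample = 16L,
                                compression = "none"), silent = TRUE)
      if (inherits(ok, "try-error"))
        stop_mitotraj("failed to write ", f, ": ", attr(ok, "condition")$message)
      written <- c(written, f)
    }
  }
  if (!is.null(truth)) {
    f1 <- file.path(dir, "truth_frames.csv")
    write.csv(truth$frames, f1, row.names = FALSE)
    f2 <- file.path(dir, "truth_cells.csv")
    write.csv(truth$cells, f2, row.names = FALSE)
    written <- c(written, f1, f2)
    if (labels && !is.null(truth$labels)) {
      for (t in seq_len(dim(truth$labels)[3])) {
        f <- file.path(dir, sprintf("labels_t%04d.tif", t))
        tiff::writeTIFF(truth$labels[, , t] / 65535, f,
                        bits.per.sample = 16L, compression = "none")
        written <- c(written, f)
      }
    }
  }
  invisible(written)
}
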