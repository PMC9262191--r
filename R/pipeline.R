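# End-to-end driver: movie -> detections -> tracks -> mitotic trajectories ->
# patches/masks -> features -> synchronization -> derived features -> project.

# Feature columns produced per cell-frame (registry order is fixed).
.ts_registry <- function(has_second, haralick) {
  base <- c("area_px", "area", "major_axis", "minor_axis", "orientation",
            "circularity", "mean_int", "std_int", "max_int", "min_int",
            "sister_distance")
  har <- if (haralick)
    paste0("har_", c("asm", "contrast", "correlation", "variance", "idm",
                     "sum_average", "sum_variance", "sum_entropy", "entropy",
                     "difference_variance", "difference_entropy", "imc1",
                     "imc2")) else character()
  sc <- if (has_second)
    c(paste0("sc_dilated_", c("mean_int", "std_int", "max_int",
                              "max_int_displacement")),
      paste0("sc_toroid_", c("mean_int", "std_int", "max_int",
                             "max_int_displacement"))) else character()
  derived <- c("derived/mean_int_norm", "derived/area_norm",
               "derived/recovery")
  c(base, har, sc, derived)
}

# Features of one cell-frame (NA row when the mask is empty).
.frame_features <- function(patch, patch2, mask, pixel_size, haralick,
                            sc_radius) {
  rf <- compute_region_features(patch, mask, pixel_size)
  out <- rf[c("area_px", "area", "major_axis", "minor_axis", "orientation",
              "circularity", "mean_int", "std_int", "max_int", "min_int")]
  if (haralick) {
    har <- if (!any(mask) || sum(mask) < 2) rep(NA_real_, 13) else {
      glcms <- lapply(glcm_offsets(), function(off)
        compute_glcm(patch, mask, levels = 64L, offset = off))
      haralick_features(glcms)
    }
    names(har) <- paste0("har_", c("asm", "contrast", "correlation",
                                   "variance", "idm", "sum_average",
                                   "sum_variance", "sum_entropy", "entropy",
                                   "difference_variance",
                                   "difference_entropy", "imc1", "imc2"))
    out <- c(out, har)
  }
  if (!is.null(patch2)) {
    dil <- second_channel_features(patch2, mask, radius = sc_radius,
                                   region = "dilated")
    tor <- second_channel_features(patch2, mask, radius = sc_radius,
                                   region = "toroid")
    names(dil) <- paste0("sc_dilated_", names(dil))
    names(tor) <- paste0("sc_toroid_", names(tor))
    out <- c(out, dil, tor)
  }
  out
}

#' Run the full mitotic-progression analysis pipeline
#'
#' Detects nuclei in every frame, tracks them backward in time, extracts
#' mitotic trajectory pairs with the default 30/60-frame window, segments the
#' central cell of every tracked patch (optionally merging external instance
#' labels with classical fallback), computes the feature time series,
#' synchronizes each pair on the IP and MA transitions with the classical
#' method, appends derived features (event-normalized series and the
#' interphase-recovery series) and single features (IP-to-MA duration,
#' angular features, interphase means, post-MA recovery slope), and returns
#' everything as a [cell_project()].
#'
#' @param movie a [movie_stack()].
#' @param sigmas LoG scales (default: resolution-derived, see
#'   [detect_movie()]).
#' @param cutoff tracking cutoff (`"auto"` or px).
#' @param n_before,n_after trajectory window (defaults 30/60 frames).
#' @param patch_size patch side (default [default_patch_size()]).
#' @param ma_threshold MA sister-distance threshold in px (default
#'   [default_ma_threshold()]).
#' @param label_images optional list of per-frame instance label matrices
#'   (e.g. an external segmenter's output); classical segmentation is the
#'   fallback wherever no label covers a detection.
#' @param haralick compute Haralick texture features (default TRUE)?
#' @param sc_radius structuring-element radius for second-channel features.
#' @param verbose print progress?
#' @return a [cell_project()]; cells are named `d<pair>_<a|b>`.
#' @export
run_pipeline <- function(movie, sigmas = NULL, cutoff = "auto",
                         n_before = 30L, n_after = 60L,
                         patch_size = default_patch_size(movie$pixel_size),
                         ma_threshold = default_ma_threshold(movie$pixel_size),
                         label_images = NULL, haralick = TRUE,
                         sc_radius = 15L, verbose = FALSE) {
  stopifnot(inherits(movie, "movie_stack"))
  say <- function(...) if (verbose) message(...)
  say("detecting nuclei in ", movie$frame_count, " frames")
  dets <- detect_movie(movie, sigmas = sigmas)
  say("tracking ", sum(vapply(dets, nrow, 0L)), " detections")
  graph <- track_movie(dets, cutoff = cutoff)
  pairs <- extract_mitotic_trajectories(graph, n_before, n_after)
  say(length(pairs), " mitotic trajectory pair(s)")
  has_second <- length(movie$channels) > 1L
  registry <- .ts_registry(has_second, haralick)
  n_frames_traj <- n_before + n_after
  div_idx <- n_before + 1L

  cells <- list()
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    dist_px <- sister_distance(pair$a, pair$b, pixel_size = 1)
    dist_um <- dist_px * movie$pixel_size
    feats <- list()
    for (d in c("a", "b")) {
      traj <- pair[[d]]
      m <- matrix(NA_real_, n_frames_traj, length(registry),
                  dimnames = list(NULL, registry))
      rows <- if (d == "a") seq_len(n_frames_traj) else
        seq(div_idx, n_frames_traj)      # pre-division rows copied from 'a'
      fails <- 0L
      for (k in rows) {
        f <- traj$frame[k]
        img <- movie$channels[[1]][, , f]
        ctr <- c(traj$y[k], traj$x[k])
        pt <- extract_patch(img, ctr, patch_size)
        mask <- NULL
        if (!is.null(label_images)) {
          mg <- merge_instance_segmentation(label_images[[f]],
                                            data.frame(y = ctr[1], x = ctr[2]),
                                            patch_size, intensity_image = img)
          mask <- mg[[1]]$mask
        }
        if (is.null(mask)) {
          seg <- segment_patch_classical(pt$patch)
          mask <- seg$mask
          if (seg$failed) fails <- fails + 1L
        }
        p2 <- if (has_second)
          extract_patch(movie$channels[[2]][, , f], ctr, patch_size)$patch
        else NULL
        vals <- .frame_features(pt$patch, p2, mask, movie$pixel_size,
                                haralick, sc_radius)
        m[k, names(vals)] <- vals
      }
      if (d == "b") m[seq_len(n_before), ] <- feats$a[seq_len(n_before), ]
      m[, "sister_distance"] <- dist_um
      feats[[d]] <- m
    }
    # classical synchronization on the shared pre-division segment
    pre <- feats$a[seq_len(n_before), c("area", "circularity", "mean_int",
                                        "std_int"), drop = FALSE]
    for (j in seq_len(ncol(pre))) {       # impute failed frames
      bad <- !is.finite(pre[, j])
      if (any(bad)) pre[bad, j] <- mean(pre[!bad, j])
    }
    sync <- if (any(!is.finite(pre)))
      sync_states(n_frames_traj, valid = FALSE)
    else synchronize_classical(pre, dist_px, div_idx,
                               ma_threshold = ma_threshold,
                               n = n_frames_traj)
    theta_ref <- if (sync$valid) {
      k <- sync$ma
      wrap_axial(atan2(-(pair$b$y[k] - pair$a$y[k]),
                       pair$b$x[k] - pair$a$x[k]) * 180 / pi)
    } else NA_real_
    for (d in c("a", "b")) {
      traj <- pair[[d]]
      m <- feats[[d]]
      if (sync$valid) {
        m[, "derived/mean_int_norm"] <-
          normalize_to_event(m[, "mean_int"], sync, "interphase_mean")
        m[, "derived/area_norm"] <-
          normalize_to_event(m[, "area"], sync, "interphase_mean")
        m[, "derived/recovery"] <- suppressWarnings(recovery_percentage(
          m[, c("area", "minor_axis", "mean_int", "std_int")], sync))
      }
      ang <- if (sync$valid)
        angular_features(m[, "orientation"], sync$ip, sync$ma, theta_ref)
      else c(sum_abs_angular_change = NA_real_,
             mean_angular_difference = NA_real_)
      single <- c(
        ip_ma_duration_min = if (sync$valid)
          (sync$ma - sync$ip) * movie$sampling_interval else NA_real_,
        ang,
        interphase_mean_int = if (sync$valid)
          mean(m[sync$states == 1L, "mean_int"], na.rm = TRUE) else NA_real_,
        interphase_area = if (sync$valid)
          mean(m[sync$states == 1L, "area"], na.rm = TRUE) else NA_real_,
        recovery_end = if (sync$valid)
          m[n_frames_traj, "derived/recovery"] else NA_real_,
        area_recovery_slope = if (sync$valid)
          regression_slope(m[, "area"], sync$ma, 5L)[["slope_per_frame"]]
        else NA_real_)
      cells[[length(cells) + 1L]] <- list(
        id = sprintf("d%03d_%s", pi, d),
        pair = pi, daughter = d,
        sibling = sprintf("d%03d_%s", pi, setdiff(c("a", "b"), d)),
        division_frame = pair$division_frame,
        frames = traj$frame,
        centroids = cbind(y = traj$y, x = traj$x),
        ts = m, single = single, sync = sync,
        metadata = movie$metadata)
    }
  }
  cell_project(cells, config = list(
    n_before = n_before, n_after = n_after, patch_size = patch_size,
    ma_threshold = ma_threshold, pixel_size = movie$pixel_size,
    sampling_interval = movie$sampling_interval, haralick = haralick,
    sc_radius = sc_radius))
}
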