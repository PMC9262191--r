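# Evaluation of pipeline output against synthetic ground truth.

#' Evaluate tracking against synthetic ground truth
#'
#' Division recovery: a ground-truth division counts as recovered when a
#' detected division lies within `tol_frames` frames and its parent within
#' `tol_px` of the mother's last position. Track purity: each detection is
#' assigned to the nearest ground-truth cell of its frame (within
#' `match_px`); a track's purity is the fraction of its detections assigned
#' to its majority cell, and the reported purity is the detection-weighted
#' mean over tracks.
#'
#' @param graph a `track_graph` from [track_movie()].
#' @param truth ground truth from [generate_movie()].
#' @param tol_frames division frame tolerance (default 1).
#' @param tol_px spatial tolerance for division matching (default 15).
#' @param match_px assignment radius for purity (default 15).
#' @return list: `division_recall`, `division_offsets`, `purity`,
#'   `n_true_divisions`, `n_detected_divisions`.
#' @export
evaluate_tracking <- function(graph, truth, tol_frames = 1, tol_px = 15,
                              match_px = 15) {
  tf <- truth$frames
  mothers <- truth$cells[!is.na(truth$cells$division_frame), ]
  offsets <- rep(NA_real_, nrow(mothers))
  if (nrow(graph$divisions)) {
    for (i in seq_len(nrow(mothers))) {
      f0 <- mothers$division_frame[i]
      pos <- tf[tf$cell_id == mothers$cell_id[i] &
                tf$frame == mothers$last_frame[i], c("y", "x")]
      cand <- graph$divisions[abs(graph$divisions$frame - f0) <= tol_frames, ,
                              drop = FALSE]
      if (!nrow(cand)) next
      best <- Inf
      for (r in seq_len(nrow(cand))) {
        pn <- graph$nodes[graph$nodes$track_id == cand$parent_track[r] &
                          graph$nodes$frame == cand$frame[r] - 1L, ]
        if (!nrow(pn)) next
        d <- sqrt((pn$y[1] - pos$y)^2 + (pn$x[1] - pos$x)^2)
        if (d <= tol_px && abs(cand$frame[r] - f0) < abs(best))
          best <- cand$frame[r] - f0
      }
      if (is.finite(best)) offsets[i] <- best
    }
  }
  # purity
  nodes <- graph$nodes
  assigned <- rep(NA_integer_, nrow(nodes))
  for (t in unique(nodes$frame)) {
    sel <- which(nodes$frame == t)
    gt <- tf[tf$frame == t, ]
    if (!nrow(gt)) next
    for (i in sel) {
      d <- sqrt((gt$y - nodes$y[i])^2 + (gt$x - nodes$x[i])^2)
      j <- which.min(d)
      if (d[j] <= match_px) assigned[i] <- gt$cell_id[j]
    }
  }
  per_track <- split(assigned, nodes$track_id)
  purities <- vapply(per_track, function(a) {
    a <- a[!is.na(a)]
    if (!length(a)) return(0)
    max(table(a)) / length(a)
  }, 0)
  weights <- vapply(per_track, length, 0L)
  list(division_recall = mean(!is.na(offsets)),
       division_offsets = offsets,
       purity = sum(purities * weights) / sum(weights),
       n_true_divisions = nrow(mothers),
       n_detected_divisions = nrow(graph$divisions))
}

#' Evaluate synchronization anchors against ground truth
#'
#' Matches each trajectory pair to the ground-truth division closest in time
#' and space and reports the absolute-frame offsets of the detected IP and MA
#' anchors from the true `ip_frame`/`ma_frame`.
#'
#' @param project a [cell_project()] from [run_pipeline()].
#' @param truth ground truth from [generate_movie()].
#' @return data.frame with one row per pair: `pair`, `valid`, `ip_offset`,
#'   `ma_offset` (frames; NA when unmatched or invalid).
#' @export
evaluate_sync <- function(project, truth) {
  mothers <- truth$cells[!is.na(truth$cells$division_frame), ]
  tf <- truth$frames
  pairs <- unique(vapply(project$cells, `[[`, 0, "pair"))
  rows <- lapply(pairs, function(pi) {
    cell <- Filter(function(cl) cl$pair == pi && cl$daughter == "a",
                   project$cells)[[1]]
    if (!cell$sync$valid)
      return(data.frame(pair = pi, valid = FALSE, ip_offset = NA_real_,
                        ma_offset = NA_real_))
    f0 <- cell$division_frame
    k <- which(cell$frames == f0)
    pos <- cell$centroids[k - 1L, ]
    best <- NA_integer_; bestd <- Inf
    for (i in seq_len(nrow(mothers))) {
      if (abs(mothers$division_frame[i] - f0) > 2) next
      gp <- tf[tf$cell_id == mothers$cell_id[i] &
               tf$frame == mothers$last_frame[i], c("y", "x")]
      d <- sqrt((gp$y - pos["y"])^2 + (gp$x - pos["x"])^2)
      if (d < bestd) { bestd <- d; best <- i }
    }
    if (is.na(best) || bestd > 20)
      return(data.frame(pair = pi, valid = TRUE, ip_offset = NA_real_,
                        ma_offset = NA_real_))
    abs_ip <- cell$frames[cell$sync$ip]
    abs_ma <- cell$frames[cell$sync$ma]
    data.frame(pair = pi, valid = TRUE,
               ip_offset = abs_ip - mothers$ip_frame[best],
               ma_offset = abs_ma - mothers$ma_frame[best])
  })
  do.call(rbind, rows)
}
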