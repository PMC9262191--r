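# Time-reversed tracking: detections are linked to their predecessors frame by
# frame, starting from the last frame, by cutting a Ward-linkage dendrogram
# over the union of current- and next-frame centroids. Two tracks meeting the
# same predecessor inside one cluster mark a cell-division event.

#' Heuristic clustering cutoff from the local point density
#'
#' Half the average distance of each object to its eight spatially nearest
#' neighbours. With fewer than nine objects, `min(8, n - 1)` neighbours are
#' used. The cutoff scales linearly with the coordinates.
#'
#' @param detections data.frame with columns `y`, `x` (>= 2 rows; a single
#'   detection returns `NA` so the caller can fall back to a user cutoff).
#' @return cutoff distance in pixels.
#' @export
heuristic_cutoff <- function(detections) {
  n <- nrow(detections)
  if (is.null(n) || n == 0L) stop_mitotraj("no detections")
  if (n == 1L) return(NA_real_)
  k <- min(8L, n - 1L)
  D <- as.matrix(dist(cbind(detections$y, detections$x)))
  knn_mean <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i], partial = k)[seq_len(k)])
  }, 0)
  0.5 * mean(knn_mean)
}

#' Link one frame to the next (time-reversed) and annotate divisions
#'
#' Clusters the union of frame-`t` and frame-`t+1` centroids by agglomerative
#' clustering with Ward's linkage, cut at `cutoff`. Within each cluster, each
#' next-frame object links to its nearest current-frame object. A current-frame
#' object claimed by exactly two next-frame objects with different track ids is
#' a division; more than two claimants are rejected (binary division model)
#' and those tracks are left unlinked. Unlinked objects start or terminate
#' tracks. Deterministic.
#'
#' @param det_t data.frame (`y`, `x`) of the current (earlier) frame.
#' @param det_next data.frame (`y`, `x`) of the already-tracked later frame.
#' @param next_ids integer track ids of the `det_next` rows.
#' @param cutoff dendrogram cut height (px), > 0.
#' @return list with `pred` (for each next-frame row, the linked current-frame
#'   row index or NA) and `divisions` (data.frame: current-frame row index,
#'   the two linked next-frame row indices).
#' @export
link_backward <- function(det_t, det_next, next_ids, cutoff) {
  stopifnot(cutoff > 0)
  n_t <- nrow(det_t); n_n <- nrow(det_next)
  pred <- rep(NA_integer_, n_n)
  divisions <- data.frame(cur = integer(), next_a = integer(),
                          next_b = integer())
  if (n_t == 0L || n_n == 0L)
    return(list(pred = pred, divisions = divisions))
  pts <- rbind(cbind(det_t$y, det_t$x), cbind(det_next$y, det_next$x))
  if (nrow(pts) == 2L) {
    cl <- if (sqrt(sum((pts[1, ] - pts[2, ])^2)) <= cutoff) c(1L, 1L)
          else c(1L, 2L)
  } else {
    hc <- hclust(dist(pts), method = "ward.D2")
    cl <- cutree(hc, h = cutoff)
  }
  is_cur <- seq_len(nrow(pts)) <= n_t
  for (g in unique(cl)) {
    cur <- which(is_cur & cl == g)
    nxt <- which(!is_cur & cl == g) - n_t
    if (length(cur) == 0L || length(nxt) == 0L) next
    # nearest current-frame object for each next-frame object
    for (j in nxt) {
      d <- sqrt((det_t$y[cur] - det_next$y[j])^2 +
                (det_t$x[cur] - det_next$x[j])^2)
      pred[j] <- cur[which.min(d)]
    }
  }
  # divisions: one predecessor claimed by exactly two distinct tracks
  claimed <- split(seq_len(n_n), pred)
  for (ci in names(claimed)) {
    js <- claimed[[ci]]
    if (length(js) < 2L) next
    ids <- next_ids[js]
    if (length(js) == 2L && ids[1] != ids[2]) {
      divisions <- rbind(divisions,
                         data.frame(cur = as.integer(ci),
                                    next_a = js[1], next_b = js[2]))
    } else {
      pred[js] <- NA_integer_   # >2 claimants (or duplicate ids): reject
    }
  }
  list(pred = pred, divisions = divisions)
}

#' Track detections backward through a movie
#'
#' Runs [link_backward()] from the last frame to the first, assigning track
#' ids and annotating division events. The division frame is the first frame
#' at which the two daughter detections exist (early anaphase). At a division
#' the parent receives a new track id so that each track is a simple chain.
#'
#' @param detections list of per-frame detection data.frames (`y`, `x`), as
#'   returned by [detect_movie()].
#' @param cutoff `"auto"` for the per-frame [heuristic_cutoff()], or a fixed
#'   distance in pixels.
#' @return object of class `track_graph`: list with `nodes` (data.frame:
#'   frame, y, x, track_id) and `divisions` (data.frame: frame, parent_track,
#'   daughter_a, daughter_b).
#' @export
track_movie <- function(detections, cutoff = "auto") {
  TT <- length(detections)
  stopifnot(TT >= 1L)
  fixed <- if (is.numeric(cutoff)) cutoff else NA_real_
  ids <- vector("list", TT)
  ids[[TT]] <- seq_len(nrow(detections[[TT]]))
  next_id <- length(ids[[TT]]) + 1L
  divisions <- data.frame(frame = integer(), parent_track = integer(),
                          daughter_a = integer(), daughter_b = integer())
  if (TT > 1L) for (t in seq(TT - 1L, 1L)) {
    det_t <- detections[[t]]
    det_n <- detections[[t + 1L]]
    n_t <- nrow(det_t)
    ids[[t]] <- rep(NA_integer_, n_t)
    if (n_t == 0L) next
    if (nrow(det_n) == 0L) {
      ids[[t]] <- seq.int(next_id, length.out = n_t)
      next_id <- next_id + n_t
      next
    }
    co <- if (!is.na(fixed)) fixed else {
      h <- heuristic_cutoff(det_t)
      if (is.na(h) || h <= 0) 50 else h
    }
    lk <- link_backward(det_t, det_n, ids[[t + 1L]], co)
    # inherit ids along single links
    single <- setdiff(which(!is.na(lk$pred)), unlist(lk$divisions[c("next_a", "next_b")]))
    for (j in single) ids[[t]][lk$pred[j]] <- ids[[t + 1L]][j]
    # divisions: parent gets a fresh id
    if (nrow(lk$divisions)) for (r in seq_len(nrow(lk$divisions))) {
      cur <- lk$divisions$cur[r]
      ids[[t]][cur] <- next_id
      divisions <- rbind(divisions, data.frame(
        frame = t + 1L, parent_track = next_id,
        daughter_a = ids[[t + 1L]][lk$divisions$next_a[r]],
        daughter_b = ids[[t + 1L]][lk$divisions$next_b[r]]))
      next_id <- next_id + 1L
    }
    # unlinked current-frame objects: new track ids (track termination)
    fresh <- which(is.na(ids[[t]]))
    if (length(fresh)) {
      ids[[t]][fresh] <- seq.int(next_id, length.out = length(fresh))
      next_id <- next_id + length(fresh)
    }
  }
  nodes <- do.call(rbind, lapply(seq_len(TT), function(t) {
    d <- detections[[t]]
    if (nrow(d) == 0L) return(NULL)
    data.frame(frame = t, y = d$y, x = d$x, track_id = ids[[t]])
  }))
  structure(list(nodes = nodes, divisions = divisions), class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  cat("track_graph: ", nrow(x$nodes), " detections, ",
      length(unique(x$nodes$track_id)), " tracks, ",
      nrow(x$divisions), " division(s)\n", sep = "")
  invisible(x)
}

#' Extract valid mitotic trajectories from a track graph
#'
#' Keeps divisions whose parent track is complete for at least `n_before`
#' frames before the division and whose daughters are both complete for at
#' least `n_after` frames from the division frame on; the windows are trimmed
#' to exactly `n_before + n_after` frames. Both daughters of a pair share the
#' identical pre-division segment. With the defaults (30, 60) and a 3-minute
#' sampling interval the windows span 90 and 180 minutes.
#'
#' @param graph a `track_graph` from [track_movie()].
#' @param n_before,n_after frames required before/after the division
#'   (defaults 30 and 60).
#' @return list of trajectory pairs; each pair is a list with `division_frame`
#'   and elements `a`, `b` of class `mitotic_trajectory` (data.frame `frame`,
#'   `y`, `x` plus attributes `division_frame`, `daughter`, `n_before`,
#'   `n_after`).
#' @export
extract_mitotic_trajectories <- function(graph, n_before = 30, n_after = 60) {
  stopifnot(inherits(graph, "track_graph"))
  nodes <- graph$nodes
  out <- list()
  if (is.null(nodes) || nrow(graph$divisions) == 0L) return(out)
  by_track <- split(nodes, nodes$track_id)
  for (r in seq_len(nrow(graph$divisions))) {
    f <- graph$divisions$frame[r]
    par <- as.character(graph$divisions$parent_track[r])
    want_pre <- seq(f - n_before, f - 1L)
    want_post <- seq(f, f + n_after - 1L)
    if (want_pre[1] < 1L) next
    ptr <- by_track[[par]]
    if (is.null(ptr) || !all(want_pre %in% ptr$frame)) next
    das <- lapply(c(a = "daughter_a", b = "daughter_b"), function(col) {
      dtr <- by_track[[as.character(graph$divisions[[col]][r])]]
      if (is.null(dtr) || !all(want_post %in% dtr$frame)) return(NULL)
      dtr[match(want_post, dtr$frame), c("frame", "y", "x")]
    })
    if (any(vapply(das, is.null, TRUE))) next
    pre <- ptr[match(want_pre, ptr$frame), c("frame", "y", "x")]
    pair <- list(division_frame = f)
    for (d in c("a", "b")) {
      traj <- rbind(pre, das[[d]])
      rownames(traj) <- NULL
      attr(traj, "division_frame") <- f
      attr(traj, "daughter") <- d
      attr(traj, "n_before") <- n_before
      attr(traj, "n_after") <- n_after
      attr(traj, "track_id") <- graph$divisions[[paste0("daughter_", d)]][r]
      class(traj) <- c("mitotic_trajectory", "data.frame")
      pair[[d]] <- traj
    }
    out[[length(out) + 1L]] <- pair
  }
  out
}
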