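# Trajectory synchronization: assign each frame a mitotic state (0 invalid,
# 1 interphase, 2 prophase..early anaphase, 3 late anaphase/telophase) and
# anchor the IP (1->2) and MA (2->3) transitions.

#' Construct a per-frame state sequence
#'
#' @param n number of frames.
#' @param ip,ma 1-based indices of the first state-2 and first state-3 frame
#'   (`ip < ma`); `NA` with `valid = FALSE` gives an all-0 (rejected)
#'   sequence.
#' @param valid is the trajectory a valid mitotic track?
#' @param low_confidence optional flag from the IP detector.
#' @return object of class `sync_states`: list with `states` (integer
#'   vector), `ip`, `ma`, `valid`, `low_confidence`.
#' @export
sync_states <- function(n, ip = NA, ma = NA, valid = !is.na(ip) && !is.na(ma),
                        low_confidence = FALSE) {
  if (isTRUE(valid)) {
    if (is.na(ip) || is.na(ma) || ip < 1 || ma <= ip || ma > n)
      stop_mitotraj("valid states need 1 <= ip < ma <= n")
    states <- rep(1L, n)
    states[ip:n] <- 2L
    states[ma:n] <- 3L
  } else {
    states <- rep(0L, n)
    ip <- ma <- NA_integer_
  }
  structure(list(states = states, ip = as.integer(ip), ma = as.integer(ma),
                 valid = isTRUE(valid), low_confidence = low_confidence),
            class = "sync_states")
}

#' @export
print.sync_states <- function(x, ...) {
  if (x$valid)
    cat("sync_states: ", length(x$states), " frames, IP at ", x$ip,
        ", MA at ", x$ma, if (x$low_confidence) " (low confidence)" else "",
        "\n", sep = "")
  else cat("sync_states: rejected track (all 0)\n")
  invisible(x)
}

#' Temporally constrained two-cluster split (TC3)
#'
#' Finds the contiguous two-segment partition of a multivariate time series
#' that minimizes the total within-cluster sum of squares,
#' `sum_{t<s} ||x_t - mu1||^2 + sum_{t>=s} ||x_t - mu2||^2`, by exhaustive
#' search over all split points -- the constrained 2-cluster optimum. Columns
#' are z-scored over the searched frames first so features with different
#' units contribute comparably. Ties return the earliest split.
#'
#' @param x numeric matrix (frames x features) or vector.
#' @param search_range candidate split indices `s` (the first frame of the
#'   second segment); default `2:nrow(x)`.
#' @return list: `split` (s), `cost` (optimal within-class SSE),
#'   `cost_constant` (single-cluster SSE), `confidence`
#'   (`cost_constant / cost`, 1 = no structure).
#' @export
tc3_split <- function(x, search_range = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop_mitotraj("need at least 2 frames to split")
  if (is.null(search_range)) search_range <- 2:n
  search_range <- sort(unique(as.integer(search_range)))
  if (any(search_range < 2L | search_range > n))
    stop_mitotraj("search_range must lie in 2..n")
  z <- zscore_cols(x)
  cs <- apply(z, 2, cumsum)                  # cumulative sums
  cs2 <- apply(z^2, 2, cumsum)               # cumulative sums of squares
  tot_s <- cs[n, ]; tot_s2 <- cs2[n, ]
  cost_of <- function(s) {
    n1 <- s - 1L; n2 <- n - n1
    s1 <- cs[n1, ]; q1 <- cs2[n1, ]
    sum(q1 - s1^2 / n1) + sum((tot_s2 - q1) - (tot_s - s1)^2 / n2)
  }
  costs <- vapply(search_range, cost_of, 0)
  best <- which.min(costs)                   # earliest on ties
  cost_constant <- sum(tot_s2 - tot_s^2 / n)
  list(split = search_range[best], cost = costs[best],
       cost_constant = cost_constant,
       confidence = if (costs[best] > 0) cost_constant / costs[best] else Inf)
}

#' Detect the interphase-to-prophase transition
#'
#' Applies [tc3_split()] to the pre-division window of the classical feature
#' quadruple (area, circularity, mean intensity, intensity standard
#' deviation): chromatin condensation makes the area drop and the intensity
#' rise, so the optimal two-segment split lands at the IP transition. Tracks
#' where the split barely improves on a constant model
#' (`confidence < min_confidence`) -- e.g. cells that never leave interphase
#' -- are flagged low-confidence, not auto-rejected.
#'
#' @param features matrix (pre-division frames x 4) of area, circularity,
#'   mean_int, std_int.
#' @param search_range passed to [tc3_split()].
#' @param min_confidence flag threshold on `cost_constant / cost`
#'   (default 1.2).
#' @return list: `ip` (first state-2 frame), `low_confidence`, `tc3` (the
#'   full [tc3_split()] result).
#' @export
detect_ip <- function(features, search_range = NULL, min_confidence = 1.2) {
  res <- tc3_split(features, search_range)
  list(ip = res$split, low_confidence = res$confidence < min_confidence,
       tc3 = res)
}

#' Reposition the MA anchor by the sister-distance heuristic
#'
#' The division frame found during tracking corresponds to early anaphase;
#' the MA transition (anaphase onset proper) is placed at the first
#' post-division frame where the centroid distance of the two daughter
#' chromatin masses exceeds `threshold`. If the threshold is never exceeded
#' the division frame is kept.
#'
#' @param distances per-frame sister centroid distances (px), aligned with
#'   the trajectory frames.
#' @param division_index 1-based index of the division frame within the
#'   trajectory.
#' @param threshold distance threshold in px (default 10 px at 0.65 um/px;
#'   scale with 0.65 / pixel_size for other resolutions).
#' @return 1-based MA index.
#' @export
reposition_ma <- function(distances, division_index, threshold = 10) {
  post <- seq(division_index, length(distances))
  hit <- post[distances[post] > threshold]
  if (length(hit)) hit[1] else division_index
}

#' Default MA distance threshold for a pixel size
#' @param pixel_size um/px.
#' @return threshold in px (10 px at 0.65 um/px, physically constant).
#' @export
default_ma_threshold <- function(pixel_size = 0.65) 10 * 0.65 / pixel_size

#' Default HMM transition matrix over states 0..3
#'
#' Only self-transitions and the forward transitions 1->2 and 2->3 are
#' allowed (probability `advance`); state 0 (invalid) is absorbing. Rows are
#' from-states 0..3.
#'
#' @param advance probability of advancing to the next state (default 0.1).
#' @return 4x4 row-stochastic matrix.
#' @export
default_transitions <- function(advance = 0.1) {
  m <- matrix(0, 4, 4, dimnames = list(0:3, 0:3))
  m["0", "0"] <- 1
  m["1", "1"] <- 1 - advance; m["1", "2"] <- advance
  m["2", "2"] <- 1 - advance; m["2", "3"] <- advance
  m["3", "3"] <- 1
  m
}

#' Viterbi decoding of per-frame state probabilities
#'
#' Decodes the most likely state sequence under an HMM whose transitions only
#' allow the monotone progression 1 -> 2 -> 3 (or the all-0 invalid path);
#' the start distribution permits states 0 and 1. Any per-frame classifier
#' can supply the probability table, making the synchronizer pluggable.
#' Decoding is in log space; ties prefer the lower state index. If the
#' winning path is the all-0 path the track is invalid; otherwise the IP/MA
#' anchors are read off the state changes (a path that never reaches state 3
#' is returned with `valid = FALSE` since both anchors are required).
#'
#' @param probs `T x 4` matrix of per-frame probabilities over states 0..3;
#'   rows must sum to 1 (tolerance 1e-6).
#' @param transitions 4x4 transition matrix, see [default_transitions()].
#' @param start length-4 start distribution (default uniform over 0 and 1).
#' @return a [sync_states()] object with attribute `path` (decoded states).
#' @export
viterbi_decode <- function(probs, transitions = default_transitions(),
                           start = c(0.5, 0.5, 0, 0)) {
  probs <- as.matrix(probs)
  TT <- nrow(probs)
  stopifnot(ncol(probs) == 4L, TT >= 1L)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_mitotraj("each probability row must sum to 1")
  if (any(rowSums(probs > 0) == 0))
    stop_mitotraj("all-zero probability column: degenerate classifier")
  lp <- log(probs)
  lt <- log(transitions)
  ls <- log(start)
  delta <- matrix(-Inf, TT, 4)
  psi <- matrix(0L, TT, 4)
  delta[1, ] <- ls + lp[1, ]
  if (TT > 1) for (t in 2:TT) {
    for (s in 1:4) {
      cand <- delta[t - 1, ] + lt[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + lp[t, s]
    }
  }
  path <- integer(TT)
  path[TT] <- which.max(delta[TT, ])
  if (TT > 1) for (t in seq(TT - 1, 1)) path[t] <- psi[t + 1, path[t + 1]]
  states <- path - 1L                        # back to labels 0..3
  if (all(states == 0L)) {
    out <- sync_states(TT, valid = FALSE)
  } else {
    ip <- which(states == 2L)[1]
    ma <- which(states == 3L)[1]
    if (is.na(ip) || is.na(ma)) out <- sync_states(TT, valid = FALSE)
    else out <- sync_states(TT, ip = ip, ma = ma)
  }
  attr(out, "path") <- states
  out
}

#' Built-in per-frame state probabilities from classical features
#'
#' A fixed-coefficient softmax model that turns the classical feature
#' quadruple plus the sister distance into per-frame probabilities over the
#' states 0..3, for use with [viterbi_decode()]: condensation evidence
#' (intensity up, area down, both z-scored over the trajectory) drives state
#' 2 over state 1, and a sister distance approaching the MA threshold drives
#' state 3. This is a deliberately simple, trainable-classifier-free stand-in
#' exposing the same interface as any learned per-frame classifier.
#'
#' @param features matrix/data.frame with columns `area`, `mean_int` (others
#'   are ignored by the default coefficients).
#' @param distances sister centroid distances (px) per frame.
#' @param ma_threshold MA distance threshold in px.
#' @param k_cond,k_dist,invalid_logit model coefficients.
#' @return `T x 4` probability matrix (states 0..3).
#' @export
builtin_state_probs <- function(features, distances, ma_threshold = 10,
                                k_cond = 2, k_dist = 1, invalid_logit = -4) {
  z <- zscore_cols(features[, c("area", "mean_int")])
  cond <- (z[, "mean_int"] - z[, "area"]) / 2
  l0 <- rep(invalid_logit, nrow(z))
  l2 <- k_cond * cond
  l1 <- -l2
  l3 <- k_dist * (distances - 0.8 * ma_threshold)
  logits <- cbind(l0, l1, l2, l3)
  p <- exp(logits - apply(logits, 1, max))
  p / rowSums(p)
}

#' Classical synchronization of a trajectory pair
#'
#' The default, classifier-free pathway: [detect_ip()] on the pre-division
#' window anchors IP, and [reposition_ma()] on the sister distances anchors
#' MA. Both daughters of a pair share the identical result.
#'
#' @param features pre-division feature matrix (frames x 4: area,
#'   circularity, mean_int, std_int) of the shared parent segment.
#' @param distances full-length sister distance series (px).
#' @param division_index index of the division frame within the trajectory.
#' @param ma_threshold MA distance threshold (px).
#' @param n total trajectory length.
#' @return a [sync_states()] object.
#' @export
synchronize_classical <- function(features, distances, division_index,
                                  ma_threshold = 10, n = length(distances)) {
  ipres <- detect_ip(features)
  ma <- reposition_ma(distances, division_index, ma_threshold)
  if (ma <= ipres$ip) return(sync_states(n, valid = FALSE))
  sync_states(n, ip = ipres$ip, ma = ma,
              low_confidence = ipres$low_confidence)
}

#' Read a manual synchronization annotation file
#'
#' CSV with columns `cell_id`, `last_interphase_frame`,
#' `early_anaphase_frame`, `reject` (0/1) -- the file-based replacement for
#' two-click GUI annotation. Frames are 1-based trajectory indices.
#'
#' @param path CSV file path.
#' @return data.frame of annotations.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop_mitotraj("annotation file not found: ", path)
  a <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "last_interphase_frame", "early_anaphase_frame",
            "reject")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop_mitotraj("annotation file lacks column(s): ",
                  paste(miss, collapse = ", "))
  a
}

#' Apply a manual annotation to a trajectory (and its sibling)
#'
#' Two clicks define the synchronization: the last frame considered
#' interphase (`last_interphase`) marks the IP transition (state 2 starts on
#' the following frame) and the early-anaphase frame (`early_anaphase`) marks
#' the MA transition (state 3 starts on the following frame). Intermediate
#' frames are classified accordingly, and the annotation is copied verbatim
#' to the sibling daughter so the pair stays consistently aligned. `reject`
#' marks the whole track invalid (all states 0).
#'
#' @param n trajectory length in frames.
#' @param last_interphase,early_anaphase 1-based trajectory frame indices
#'   with `last_interphase < early_anaphase`.
#' @param reject reject the whole trajectory?
#' @return list with identical `a` and `b` [sync_states()] (the copy rule).
#' @export
apply_annotation <- function(n, last_interphase = NA, early_anaphase = NA,
                             reject = FALSE) {
  if (isTRUE(reject)) {
    s <- sync_states(n, valid = FALSE)
    return(list(a = s, b = s))
  }
  ip <- last_interphase + 1L
  ma <- early_anaphase + 1L
  if (is.na(ip) || is.na(ma) || ma <= ip || ip < 2L || ma > n)
    stop_mitotraj("rejected annotation: need last_interphase < ",
                  "early_anaphase inside the trajectory (got ",
                  last_interphase, ", ", early_anaphase, ")")
  s <- sync_states(n, ip = ip, ma = ma)
  list(a = s, b = s)
}
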