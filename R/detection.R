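# Nucleus detection via multi-scale Laplacian-of-Gaussian filtering.

# Scale-normalized negated LoG kernel: positive response for bright blobs.
.log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  d <- (-r):r
  X <- matrix(d, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  Y <- t(X)
  g <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  g <- g / sum(g)
  lap <- ((X^2 + Y^2 - 2 * sigma^2) / sigma^4) * g
  lap <- lap - mean(lap)              # zero DC: invariant to intensity offsets
  -sigma^2 * lap                      # negate + scale-normalize
}

#' Detect nucleus centroids with a multi-scale Laplacian of Gaussian
#'
#' Convolves the frame with scale-normalized negated LoG kernels over a set of
#' scales, finds local maxima of the response that exceed `threshold_rel`
#' times the per-frame maximum response, merges maxima closer than
#' `sigma * sqrt(2)` (keeping the stronger response) and refines each centroid
#' to sub-pixel precision by the response-weighted centroid of its 3x3
#' neighbourhood. The relative threshold makes detection invariant to global
#' intensity scaling, and the zero-DC kernel to constant offsets. A blank
#' frame yields an empty detection table. Deterministic.
#'
#' @param image numeric matrix (one grayscale frame).
#' @param sigmas vector of LoG scales (px), e.g. from
#'   [make_resolution_preset()].
#' @param threshold_rel detection threshold relative to the per-frame maximum
#'   response (default 0.1).
#' @return data.frame with columns `y`, `x` (sub-pixel, 1-based), `scale`,
#'   `response`, ordered by decreasing response.
#' @export
detect_nuclei <- function(image, sigmas, threshold_rel = 0.1) {
  stopifnot(is.matrix(image), is.numeric(sigmas), length(sigmas) >= 1)
  sigmas <- sort(sigmas)
  if (any(sigmas <= 0)) stop_mitotraj("scales must be > 0")
  H <- nrow(image); W <- ncol(image)
  if (diff(range(image)) == 0) {
    return(data.frame(y = numeric(), x = numeric(), scale = numeric(),
                      response = numeric()))
  }
  cand <- vector("list", length(sigmas))
  responses <- vector("list", length(sigmas))
  gmax <- -Inf
  for (si in seq_along(sigmas)) {
    k <- .log_kernel(sigmas[si])
    resp <- EBImage::filter2(image, k, boundary = "replicate")
    responses[[si]] <- resp
    gmax <- max(gmax, max(resp))
  }
  if (!is.finite(gmax) || gmax <= 0) {
    return(data.frame(y = numeric(), x = numeric(), scale = numeric(),
                      response = numeric()))
  }
  # floor guards against numerically-flat responses
  thr <- max(threshold_rel * gmax, 1e-9 * diff(range(image)))
  for (si in seq_along(sigmas)) {
    resp <- responses[[si]]
    # strict 8-neighbour local maxima in the frame interior
    ok <- matrix(FALSE, H, W)
    core <- resp[2:(H - 1), 2:(W - 1)]
    ok[2:(H - 1), 2:(W - 1)] <-
      core > thr &
      core >= resp[1:(H - 2), 2:(W - 1)] & core >= resp[3:H, 2:(W - 1)] &
      core >= resp[2:(H - 1), 1:(W - 2)] & core >= resp[2:(H - 1), 3:W] &
      core >= resp[1:(H - 2), 1:(W - 2)] & core >= resp[1:(H - 2), 3:W] &
      core >= resp[3:H, 1:(W - 2)] & core >= resp[3:H, 3:W]
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      # sub-pixel refinement: response-weighted centroid of the 3x3 patch
      ys <- xs <- numeric(nrow(idx))
      for (i in seq_len(nrow(idx))) {
        r <- idx[i, 1]; c <- idx[i, 2]
        w <- resp[(r - 1):(r + 1), (c - 1):(c + 1)]
        w <- pmax(w, 0)
        sw <- sum(w)
        if (sw > 0) {
          ys[i] <- sum(w * ((r - 1):(r + 1))) / sw
          xs[i] <- sum(w * matrix((c - 1):(c + 1), 3, 3, byrow = TRUE)) / sw
        } else {
          ys[i] <- r; xs[i] <- c
        }
      }
      cand[[si]] <- data.frame(y = ys, x = xs, scale = sigmas[si],
                               response = resp[idx])
    }
  }
  det <- do.call(rbind, cand)
  if (is.null(det) || nrow(det) == 0L) {
    return(data.frame(y = numeric(), x = numeric(), scale = numeric(),
                      response = numeric()))
  }
  det <- det[order(-det$response, det$y, det$x), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    acc <- det[keep, , drop = FALSE]
    dd <- sqrt((acc$y - det$y[i])^2 + (acc$x - det$x[i])^2)
    # merge radius from the larger scale of each candidate pair
    if (all(dd >= pmax(acc$scale, det$scale[i]) * sqrt(2))) keep[i] <- TRUE
  }
  det <- det[keep, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Derive LoG detection settings from the image resolution
#'
#' For a nucleus of expected diameter `d` (um) imaged at `pixel_size` (um/px),
#' the LoG response of a solid disk peaks at `sigma = radius / sqrt(2)`, i.e.
#' at `d / (2 * sqrt(2) * pixel_size)` pixels. The preset centres the scale
#' range there and spans +/-40% (5 scales), with the default relative
#' threshold of 0.1.
#'
#' @param pixel_size_um pixel size in um/px (> 0).
#' @param expected_diameter_um expected nucleus diameter in um (> 0).
#' @return list with `sigmas` (vector of scales in px) and `threshold_rel`.
#' @export
make_resolution_preset <- function(pixel_size_um, expected_diameter_um) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_mitotraj("'pixel_size_um' must be > 0")
  if (!is.numeric(expected_diameter_um) || expected_diameter_um <= 0)
    stop_mitotraj("'expected_diameter_um' must be > 0")
  center <- expected_diameter_um / (2 * sqrt(2) * pixel_size_um)
  list(sigmas = seq(0.6, 1.4, length.out = 5) * center,
       threshold_rel = 0.1)
}

#' Detect nuclei in every frame of a movie
#'
#' Applies [detect_nuclei()] to each chromatin frame. The default scale range
#' is wider at the lower end than [make_resolution_preset()] so that condensed
#' mitotic chromatin and freshly separated sister masses (roughly half the
#' interphase diameter) are still detected.
#'
#' @param movie a [movie_stack()].
#' @param sigmas scales in px; default spans 0.35-1.4 times the interphase
#'   blob scale for `expected_diameter_um`.
#' @param expected_diameter_um expected interphase nucleus diameter (um).
#' @param threshold_rel relative detection threshold.
#' @return list (length = frames) of detection data.frames.
#' @export
detect_movie <- function(movie, sigmas = NULL, expected_diameter_um = 12,
                         threshold_rel = 0.1) {
  stopifnot(inherits(movie, "movie_stack"))
  if (is.null(sigmas)) {
    center <- expected_diameter_um / (2 * sqrt(2) * movie$pixel_size)
    sigmas <- exp(seq(log(0.35 * center), log(1.4 * center), length.out = 6))
  }
  lapply(seq_len(movie$frame_count), function(t)
    detect_nuclei(movie$channels[[1]][, , t], sigmas, threshold_rel))
}
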