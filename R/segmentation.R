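# Central-cell segmentation of tracked detections: square patch crop, 5x5
# median filter, modified Otsu threshold, two-seed watershed on the inverted
# Euclidean distance map, optional merge with external instance labels.

#' Crop a square patch around a detection
#'
#' Side length `patch_size`; out-of-image parts are padded by edge
#' replication. The crop origin (1-based frame coordinates of the patch's
#' first row/col, possibly outside the image) is recorded so patch features
#' can be mapped back to frame coordinates.
#'
#' @param image numeric frame matrix.
#' @param center `c(y, x)` centre in frame coordinates.
#' @param patch_size even patch side length in px.
#' @return list: `patch` (matrix), `origin` (`c(y, x)`), `center_in_patch`.
#' @export
extract_patch <- function(image, center, patch_size = 96L) {
  H <- nrow(image); W <- ncol(image)
  half <- patch_size %/% 2L
  cy <- round(center[1]); cx <- round(center[2])
  rows <- (cy - half + 1L):(cy + (patch_size - half))
  cols <- (cx - half + 1L):(cx + (patch_size - half))
  rr <- clamp(rows, 1L, H)
  cc <- clamp(cols, 1L, W)
  list(patch = image[rr, cc, drop = FALSE],
       origin = c(rows[1], cols[1]),
       center_in_patch = c(cy - rows[1] + 1L, cx - cols[1] + 1L))
}

#' Default patch size for a given resolution
#'
#' 96 px at 0.65 um/px, scaled inversely with the pixel size and rounded to an
#' even number, so the field of view around each cell is physically constant
#' (one HeLa-sized nucleus plus margin).
#'
#' @param pixel_size um/px.
#' @return even integer patch side.
#' @export
default_patch_size <- function(pixel_size = 0.65) {
  2L * round(96 * 0.65 / pixel_size / 2)
}

# 5x5 median filter on raw intensities (EBImage works on [0,1] ranges).
.median5 <- function(patch) {
  mx <- max(patch, 1)
  EBImage::medianFilter(patch / mx, size = 2L) * mx
}

#' Otsu threshold over a 256-bin histogram
#'
#' The threshold maximizing the between-class variance over a 256-bin uniform
#' histogram spanning the patch's min-max range (dtype independent; invariant
#' up to binning to intensity scaling and equivariant to offsets). Returns the
#' intensity value of the chosen bin boundary. Ties take the lowest boundary.
#'
#' @param patch numeric matrix/vector with at least two distinct values.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(patch) {
  v <- as.numeric(patch)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop_mitotraj("constant patch: Otsu threshold undefined")
  nbins <- 256L
  bin <- pmin(floor((v - rng[1]) / diff(rng) * nbins), nbins - 1L)  # 0..255
  h <- tabulate(bin + 1L, nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)[-nbins]                 # class weights for cuts 1..255
  m0 <- cumsum(p * mids)[-nbins]
  mt <- sum(p * mids)
  valid <- w0 > 0 & w0 < 1
  bc <- rep(-Inf, nbins - 1L)
  bc[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bc)                      # earliest maximum
  rng[1] + k / nbins * diff(rng)          # upper edge of bin k
}

#' Classical central-cell segmentation of a patch
#'
#' Pipeline: (1) 5x5 median filter; (2) binarize at the arithmetic mean of the
#' Otsu threshold and the minimum filtered intensity in the central square
#' covering `center_fraction` of the patch side -- the lowered threshold keeps
#' a dim central cell that a plain Otsu threshold would remove next to a
#' brighter neighbour; (3) fill holes; (4) two-seed watershed (one seed at the
#' patch centre, one covering the patch border) on the inverted Euclidean
#' distance map of the binarization; (5) return the centre-seed region
#' intersected with the binarization, keeping the 4-connected component at the
#' patch centre. The mask is invariant to global intensity scaling (Otsu and
#' the centre minimum scale together).
#'
#' @param patch numeric patch matrix.
#' @param center_fraction side fraction of the central square used for the
#'   minimum-intensity term (default 0.5).
#' @return list: `mask` (logical matrix), `failed` (TRUE for a degenerate,
#'   empty segmentation).
#' @export
segment_patch_classical <- function(patch, center_fraction = 0.5) {
  H <- nrow(patch); W <- ncol(patch)
  empty <- list(mask = matrix(FALSE, H, W), failed = TRUE)
  if (diff(range(patch)) == 0) return(empty)
  f <- .median5(patch)
  ch <- round(H * center_fraction / 2); cw <- round(W * center_fraction / 2)
  rows <- clamp((H %/% 2L - ch + 1L):(H %/% 2L + ch), 1L, H)
  cols <- clamp((W %/% 2L - cw + 1L):(W %/% 2L + cw), 1L, W)
  min_center <- min(f[rows, cols])
  to <- try(otsu_threshold(f), silent = TRUE)
  if (inherits(to, "try-error")) return(empty)
  thr <- (to + min_center) / 2
  bin <- f > thr
  if (!any(bin)) return(empty)
  bin <- EBImage::fillHull(bin) > 0
  edt <- EBImage::distmap(EBImage::Image(bin * 1))
  edt <- matrix(as.numeric(edt), H, W)
  seeds <- matrix(0L, H, W)
  seeds[1, ] <- 2L; seeds[H, ] <- 2L; seeds[, 1] <- 2L; seeds[, W] <- 2L
  cy <- H %/% 2L; cx <- W %/% 2L
  seeds[cy, cx] <- 1L
  ws <- .seeded_watershed_cpp(-edt, seeds)
  mask <- ws == 1L & bin
  if (!any(mask)) return(empty)
  # keep the 4-connected component containing (or nearest within 5 px of)
  # the patch centre
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), H, W)
  target <- lab[cy, cx]
  if (target == 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    dd <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
    if (min(dd) > 5) return(empty)
    target <- lab[idx[which.min(dd), , drop = FALSE]]
  }
  mask <- lab == target
  mask <- EBImage::fillHull(mask * 1) > 0
  list(mask = mask, failed = FALSE)
}

#' Merge an external instance segmentation with tracked detections
#'
#' For each detection, the label image is cropped with the same patch geometry
#' as the classical pipeline and only the instance found at (or nearest to,
#' within `r` px of) the patch centre is kept, excluding neighbouring
#' instances. Detections with no instance near the centre fall back to
#' [segment_patch_classical()] on the intensity patch and are flagged.
#'
#' @param label_image integer label matrix (0 = background), same size as the
#'   intensity frame.
#' @param detections data.frame (`y`, `x`) of tracked detections in the frame.
#' @param patch_size patch side length.
#' @param intensity_image intensity frame used for the classical fallback.
#' @param r centre search radius in px (default 5).
#' @return list per detection: `mask`, `fallback` (logical), `origin`.
#' @export
merge_instance_segmentation <- function(label_image, detections,
                                        patch_size = 96L,
                                        intensity_image = NULL, r = 5) {
  if (!is.null(intensity_image) &&
      !identical(dim(label_image), dim(intensity_image)))
    stop_mitotraj("label image dimensions differ from the frame dimensions")
  out <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    ctr <- c(detections$y[i], detections$x[i])
    lp <- extract_patch(label_image, ctr, patch_size)
    cy <- lp$center_in_patch[1]; cx <- lp$center_in_patch[2]
    lab <- lp$patch
    target <- lab[cy, cx]
    if (target == 0) {
      idx <- which(lab > 0, arr.ind = TRUE)
      if (nrow(idx)) {
        dd <- sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)
        if (min(dd) <= r) target <- lab[idx[which.min(dd), , drop = FALSE]]
      }
    }
    if (target > 0) {
      out[[i]] <- list(mask = lab == target, fallback = FALSE,
                       origin = lp$origin)
    } else {
      mask <- matrix(FALSE, nrow(lab), ncol(lab))
      if (!is.null(intensity_image)) {
        ip <- extract_patch(intensity_image, ctr, patch_size)
        mask <- segment_patch_classical(ip$patch)$mask
      }
      out[[i]] <- list(mask = mask, fallback = TRUE, origin = lp$origin)
    }
  }
  out
}
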