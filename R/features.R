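# Per-frame quantitative features of segmented cells: classical region
# features, Haralick texture features from 64-level co-occurrence matrices,
# and second-channel features on morphologically derived masks.

# Chain-code perimeter of the 8-connected boundary contour, with the
# Vossepoel-Smeulders step weights (0.948 straight, 1.340 diagonal) that make
# the digital contour length an unbiased estimate of the true perimeter, so
# circularity of a rasterized disk stays close to (and never far above) 1.
.mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) return(NA_real_)
  total <- 0
  for (ct in oc) {
    if (nrow(ct) < 2L) { total <- total + 4 * 0.948; next }
    d <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
    steps <- abs(d[, 1]) + abs(d[, 2])
    total <- total + 0.948 * sum(steps == 1) + 1.340 * sum(steps == 2)
  }
  total
}

#' Classical region features of a segmented cell
#'
#' Area (px^2 and um^2), centroid, major/minor axis lengths and orientation of
#' the intensity-free equivalent ellipse (from second central moments of the
#' mask, with the 1/12 pixel-variance correction), circularity
#' `4*pi*area / perimeter^2` with an 8-connected chain-code perimeter, and
#' intensity statistics over the mask. Orientation is axial, degrees in
#' [-90, 90), measured counterclockwise from the image x (column) axis.
#' An empty mask yields all-`NA` features (missingness is propagated, never
#' zero-filled).
#'
#' @param patch numeric intensity patch.
#' @param mask logical mask of the central cell.
#' @param pixel_size um/px.
#' @return named numeric vector: `area_px`, `area`, `centroid_y`,
#'   `centroid_x`, `major_axis`, `minor_axis` (um), `orientation` (deg),
#'   `circularity`, `mean_int`, `std_int`, `max_int`, `min_int`.
#' @export
compute_region_features <- function(patch, mask, pixel_size = 1) {
  nm <- c("area_px", "area", "centroid_y", "centroid_x", "major_axis",
          "minor_axis", "orientation", "circularity", "mean_int", "std_int",
          "max_int", "min_int")
  if (!any(mask)) return(setNames(rep(NA_real_, length(nm)), nm))
  idx <- which(mask, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  n <- length(ys)
  cy <- mean(ys); cx <- mean(xs)
  mu_rr <- mean((ys - cy)^2) + 1 / 12
  mu_cc <- mean((xs - cx)^2) + 1 / 12
  mu_rc <- mean((ys - cy) * (xs - cx))
  common <- sqrt((mu_cc - mu_rr)^2 + 4 * mu_rc^2)
  major <- 2 * sqrt(2) * sqrt(mu_cc + mu_rr + common)
  minor <- 2 * sqrt(2) * sqrt(max(mu_cc + mu_rr - common, 0))
  # math convention: x = col, y = -row
  orient <- wrap_axial(0.5 * atan2(-2 * mu_rc, mu_cc - mu_rr) * 180 / pi)
  per <- .mask_perimeter(mask)
  circ <- if (is.na(per) || per <= 0) NA_real_ else 4 * pi * n / per^2
  vals <- patch[mask]
  c(area_px = n, area = n * pixel_size^2, centroid_y = cy, centroid_x = cx,
    major_axis = major * pixel_size, minor_axis = minor * pixel_size,
    orientation = orient, circularity = circ,
    mean_int = mean(vals), std_int = if (n > 1) sd(vals) else 0,
    max_int = max(vals), min_int = min(vals))
}

#' Gray-level co-occurrence matrix with background transitions removed
#'
#' The patch is quantized to `levels` uniform bins over its min-max intensity
#' range (making texture invariant to linear intensity scaling across
#' platforms) and pixel pairs `(p, p + offset)` are counted only when both
#' pixels lie inside the mask, i.e. background-to-foreground and
#' background-to-background transitions are removed. No symmetrization is
#' applied beyond the chosen offset set.
#'
#' @param patch numeric intensity patch.
#' @param mask logical mask; needs at least 2 pixels.
#' @param levels number of gray levels (default 64).
#' @param offset `c(dy, dx)` pixel offset, e.g. `c(0, 1)`.
#' @return `levels x levels` count matrix with attribute `offset`; entry
#'   `[i, j]` counts pairs with level `i` at `p` and level `j` at `p+offset`
#'   (levels 1-based).
#' @export
compute_glcm <- function(patch, mask, levels = 64L, offset = c(0L, 1L)) {
  if (sum(mask) < 2L) stop_mitotraj("mask must contain at least 2 pixels")
  rng <- range(patch)
  q <- if (diff(rng) == 0) matrix(0L, nrow(patch), ncol(patch)) else
    pmin(floor((patch - rng[1]) / diff(rng) * levels), levels - 1L)
  H <- nrow(patch); W <- ncol(patch)
  dy <- offset[1]; dx <- offset[2]
  r1 <- max(1L, 1L - dy):min(H, H - dy)
  c1 <- max(1L, 1L - dx):min(W, W - dx)
  if (length(r1) == 0L || length(c1) == 0L)
    return(structure(matrix(0, levels, levels), offset = offset))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dy, c1 + dx, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dy, c1 + dx, drop = FALSE]
  counts <- tabulate(a[ok] * levels + b[ok] + 1L, nbins = levels * levels)
  structure(matrix(counts, levels, levels, byrow = TRUE), offset = offset)
}

# The 13 primary Haralick statistics of one normalized GLCM. Gray levels are
# indexed 1..G. Entropies (sum/difference/overall) are in bits (log2); the
# information measures of correlation use natural logarithms as in the
# original definitions. 0*log(0) is taken as 0. Correlation is undefined
# (NA) for a degenerate matrix with zero marginal variance.
.haralick_one <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(G) * px); my <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(G) - my)^2 * py))
  pxy_sum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), 0)
  pxy_dif <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), 0)
  l2 <- function(p) ifelse(p > 0, log2(p), 0)
  ln <- function(p) ifelse(p > 0, log(p), 0)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx == 0 || sy == 0) NA_real_ else
    (sum(i * j * P) - mx * my) / (sx * sy)
  variance <- sum((i - mx)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  ks <- 2:(2 * G)
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(pxy_sum * l2(pxy_sum))
  entropy <- -sum(P * l2(P))
  kd <- 0:(G - 1)
  dmean <- sum(kd * pxy_dif)
  difference_variance <- sum((kd - dmean)^2 * pxy_dif)
  difference_entropy <- -sum(pxy_dif * l2(pxy_dif))
  hxy <- -sum(P * ln(P))
  hx <- -sum(px * ln(px)); hy <- -sum(py * ln(py))
  pij <- outer(px, py)
  hxy1 <- -sum(P * ln(pij))
  hxy2 <- -sum(pij * ln(pij))
  imc1 <- if (max(hx, hy) == 0) NA_real_ else (hxy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2)
}

#' Haralick texture features averaged over the standard offsets
#'
#' Each co-occurrence matrix is normalized to sum 1 and the 13 primary
#' Haralick statistics (angular second moment, contrast, correlation,
#' variance, inverse difference moment, sum average/variance/entropy, entropy,
#' difference variance/entropy, and the two information measures of
#' correlation) are computed, then averaged across the offsets. The
#' conventional offset set is `(0,1), (1,0), (1,1), (-1,1)`. For a degenerate
#' matrix (single nonzero cell) the correlation is flagged missing while the
#' other statistics are computed.
#'
#' @param glcm_set list of GLCMs from [compute_glcm()] (typically 4).
#' @return named numeric vector of the 13 averaged statistics.
#' @export
haralick_features <- function(glcm_set) {
  stopifnot(is.list(glcm_set), length(glcm_set) >= 1L)
  per <- lapply(glcm_set, function(g) {
    s <- sum(g)
    if (s == 0) stop_mitotraj("empty co-occurrence matrix")
    .haralick_one(g / s)
  })
  Reduce(`+`, per) / length(per)
}

#' The standard GLCM offset set
#' @return list of the four `c(dy, dx)` offsets.
#' @export
glcm_offsets <- function() list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))

#' Second-channel features on masks derived from the chromatin segmentation
#'
#' The chromatin mask is morphologically dilated and/or eroded with a
#' disk-shaped structuring element of radius `radius` px; features can be
#' computed on the dilated mask, the eroded mask or their set difference
#' (the toroidal region), which probes the spindle-region signal around the
#' chromatin. `max_int_displacement` is the Euclidean distance (px) from the
#' region's intensity maximum to the chromatin-mask centroid -- rising values
#' track astral/polar signal displacement.
#'
#' @param patch2 second-channel intensity patch.
#' @param mask chromatin mask (logical).
#' @param radius disk radius in px (default 15; radius 0 with
#'   `region = "dilated"` reproduces plain mask statistics).
#' @param region `"dilated"`, `"eroded"` or `"toroid"`.
#' @return named vector `mean_int`, `std_int`, `max_int`,
#'   `max_int_displacement`; all `NA` if the region is empty.
#' @export
second_channel_features <- function(patch2, mask, radius = 15,
                                    region = c("dilated", "eroded", "toroid")) {
  region <- match.arg(region)
  nm <- c("mean_int", "std_int", "max_int", "max_int_displacement")
  if (!any(mask)) return(setNames(rep(NA_real_, 4), nm))
  if (radius > 0) {
    brush <- EBImage::makeBrush(2 * as.integer(radius) + 1L, shape = "disc")
    dil <- EBImage::dilate(mask * 1, brush) > 0
    ero <- EBImage::erode(mask * 1, brush) > 0
  } else {
    dil <- ero <- mask
  }
  reg <- switch(region, dilated = dil, eroded = ero, toroid = dil & !ero)
  if (!any(reg)) return(setNames(rep(NA_real_, 4), nm))
  idx <- which(mask, arr.ind = TRUE)
  ctr <- c(mean(idx[, 1]), mean(idx[, 2]))
  vals <- patch2[reg]
  ridx <- which(reg, arr.ind = TRUE)
  top <- ridx[which.max(vals), ]
  c(mean_int = mean(vals),
    std_int = if (length(vals) > 1) sd(vals) else 0,
    max_int = max(vals),
    max_int_displacement = sqrt(sum((top - ctr)^2)))
}

#' Sister chromatin-mass centroid distance over time
#'
#' Per-frame Euclidean distance between the centroids of the two daughter
#' trajectories, in micrometres. Pre-division frames are 0 by definition
#' (a single chromatin mass).
#'
#' @param traj_a,traj_b the two `mitotic_trajectory` objects of one pair.
#' @param pixel_size um/px.
#' @return numeric vector, one value per trajectory frame.
#' @export
sister_distance <- function(traj_a, traj_b, pixel_size = 1) {
  stopifnot(identical(traj_a$frame, traj_b$frame))
  d <- sqrt((traj_a$y - traj_b$y)^2 + (traj_a$x - traj_b$x)^2) * pixel_size
  f <- attr(traj_a, "division_frame")
  if (!is.null(f)) d[traj_a$frame < f] <- 0
  d
}

#' Angular features of the metaphase plate
#'
#' From the chromatin-mask major-axis orientation series `theta(t)` (axial,
#' degrees) between the IP and MA anchors: the per-step orientation change is
#' wrapped into [-90, 90) (an axis has no head or tail, so a change from 88
#' to -88 degrees is 4 degrees, not 176), and
#' `sum_abs_angular_change = sum(|delta|)` measures total plate rotation;
#' `mean_angular_difference` is the mean absolute wrapped difference between
#' `theta(t)` and a reference axis (conventionally the sister-separation axis
#' at MA). Fewer than 2 frames between the anchors flags both as missing.
#'
#' @param theta orientation series in degrees, one value per frame.
#' @param ip,ma 1-based anchor indices into `theta` (frames `[ip, ma)` are
#'   used).
#' @param theta_ref reference axis in degrees.
#' @return named vector `sum_abs_angular_change`, `mean_angular_difference`.
#' @export
angular_features <- function(theta, ip, ma, theta_ref) {
  if (is.na(ip) || is.na(ma) || ma - ip < 2)
    return(c(sum_abs_angular_change = NA_real_,
             mean_angular_difference = NA_real_))
  d <- wrap_axial(diff(theta[ip:ma]))      # MA - IP rotation steps
  th <- theta[ip:(ma - 1)]
  c(sum_abs_angular_change = sum(abs(d), na.rm = TRUE),
    mean_angular_difference = mean(abs(wrap_axial(th - theta_ref)),
                                   na.rm = TRUE))
}
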