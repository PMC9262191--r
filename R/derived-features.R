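# Derived feature time series: smoothing, event-anchored normalization,
# windowed regression slopes and the interphase-recovery feature.

#' Smooth a feature time series
#'
#' Window must be odd and no longer than the series. Output has the same
#' length as the input; at the edges the window is truncated to the available
#' samples (the convention of the classical moving-average smoother: the
#' first value of a window-3 moving average is the mean of the first two
#' samples). A constant series is unchanged by every method; window 1 is the
#' identity.
#'
#' @param x numeric series.
#' @param window odd window size, `<= length(x)`.
#' @param method `"moving_average"`, `"lowess"` or `"savitzky_golay"`.
#' @return smoothed series, same length.
#' @export
smooth_series <- function(x, window = 5L,
                          method = c("moving_average", "lowess",
                                     "savitzky_golay")) {
  method <- match.arg(method)
  n <- length(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_mitotraj("'window' must be odd")
  if (window > n) stop_mitotraj("'window' (", window,
                                ") exceeds series length (", n, ")")
  if (window == 1L) return(x)
  switch(method,
    moving_average = {
      h <- (window - 1L) %/% 2L
      vapply(seq_len(n), function(i) {
        mean(x[max(1L, i - h):min(n, i + h)])
      }, 0)
    },
    lowess = {
      stats::lowess(seq_len(n), x, f = window / n, iter = 0)$y
    },
    savitzky_golay = {
      as.numeric(signal::sgolayfilt(x, p = min(2L, window - 1L), n = window))
    })
}

#' Normalize a series to a cell-cycle event
#'
#' Divides the series by the mean over the cell's own interphase frames
#' (`mode = "interphase_mean"`) or by the value at the first late-anaphase
#' frame (`mode = "first_late_anaphase"`, which is exactly 1 at the MA
#' anchor by construction). Absolute feature values differ between
#' microscopes and acquisition settings; these single-cell normalizations
#' make time series comparable across experiments. A zero denominator yields
#' an all-`NA` series with attribute `failed = TRUE`.
#'
#' @param x numeric series (one value per trajectory frame).
#' @param sync a valid [sync_states()] for the same frames.
#' @param mode `"interphase_mean"` or `"first_late_anaphase"`.
#' @return normalized series.
#' @export
normalize_to_event <- function(x, sync,
                               mode = c("interphase_mean",
                                        "first_late_anaphase")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sync, "sync_states"), length(x) == length(sync$states))
  if (!sync$valid) stop_mitotraj("cannot normalize a rejected trajectory")
  denom <- switch(mode,
    interphase_mean = mean(x[sync$states == 1L], na.rm = TRUE),
    first_late_anaphase = x[sync$ma])
  if (!is.finite(denom) || denom == 0) {
    out <- rep(NA_real_, length(x))
    attr(out, "failed") <- TRUE
    return(out)
  }
  x / denom
}

#' Windowed regression slope at an anchor
#'
#' Ordinary-least-squares slope of the feature values against the frame index
#' over `[anchor, anchor + window)` -- e.g. the initial recovery rate of a
#' feature immediately after anaphase onset. Missing values are dropped; with
#' fewer than 2 remaining points the slope is `NA`.
#'
#' @param x numeric series.
#' @param anchor 1-based start index of the window.
#' @param window window length in frames (>= 2).
#' @param sampling_interval optional minutes/frame; if given, the slope is
#'   also returned per minute.
#' @return named vector `slope_per_frame` (and `slope_per_min` if an
#'   interval was given).
#' @export
regression_slope <- function(x, anchor, window = 5L,
                             sampling_interval = NULL) {
  if (window < 2L) stop_mitotraj("'window' must be >= 2")
  idx <- anchor:min(length(x), anchor + window - 1L)
  t <- idx[!is.na(x[idx])]
  v <- x[t]
  slope <- if (length(t) < 2L) NA_real_ else {
    tm <- t - mean(t)
    sum(tm * (v - mean(v))) / sum(tm^2)
  }
  out <- c(slope_per_frame = slope)
  if (!is.null(sampling_interval))
    out <- c(out, slope_per_min = slope / sampling_interval)
  out
}

#' Interphase-recovery time series
#'
#' For each post-mitotic (state-3) frame, the absolute percentage deviation of
#' each selected feature from that cell's own interphase mean is computed,
#' deviations are clipped at 100% (so intensity overshoots keep the scale
#' interpretable), averaged over the selected features, and reported as the
#' complement: `R(t) = 100 - mean_f min(100, |v_f(t) - mu_f| / mu_f * 100)`.
#' `R = 100` exactly when every selected feature equals its interphase mean
#' (full recovery); `R` is always in [0, 100]. The conventional feature set
#' is area, minor axis length, mean intensity and intensity standard
#' deviation. Features with a zero interphase mean are dropped from the
#' average with a warning. Frames before MA are `NA`.
#'
#' @param features matrix/data.frame (frames x selected features).
#' @param sync a valid [sync_states()].
#' @param clip clip per-feature deviations at 100% (default TRUE)?
#' @return numeric series (percent), `NA` outside state-3 frames.
#' @export
recovery_percentage <- function(features, sync, clip = TRUE) {
  stopifnot(inherits(sync, "sync_states"))
  f <- as.matrix(features)
  if (!sync$valid) stop_mitotraj("recovery needs a valid synchronized track")
  stopifnot(nrow(f) == length(sync$states))
  inter <- sync$states == 1L
  mu <- colMeans(f[inter, , drop = FALSE], na.rm = TRUE)
  drop <- !is.finite(mu) | mu == 0
  if (any(drop)) {
    warning("dropping feature(s) with zero interphase mean: ",
            paste(colnames(f)[drop], collapse = ", "))
    f <- f[, !drop, drop = FALSE]
    mu <- mu[!drop]
    if (ncol(f) == 0L) return(rep(NA_real_, length(sync$states)))
  }
  dev <- abs(sweep(f, 2, mu, "-")) / rep(abs(mu), each = nrow(f)) * 100
  if (clip) dev <- pmin(dev, 100)
  r <- 100 - rowMeans(dev)
  r[sync$states != 3L] <- NA_real_
  r
}
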