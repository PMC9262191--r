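# Internal helpers shared across modules.

# Natural sort: numeric runs inside file names compare numerically, so
# "t2" < "t10". Used when ordering frame files.
natural_order <- function(x) {
  pieces <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  n <- max(lengths(pieces))
  keys <- lapply(seq_len(n), function(i) {
    part <- vapply(pieces, function(p) if (length(p) >= i) p[i] else "", "")
    num <- suppressWarnings(as.numeric(part))
    if (all(!is.na(num) | part == "")) {   # all non-empty pieces numeric
      num[is.na(num)] <- -Inf
      num
    } else part
  })
  do.call(order, keys)
}

# Wrap an axial angle (orientation of an undirected axis) into [-90, 90).
wrap_axial <- function(theta) {
  ((theta + 90) %% 180) - 90
}

# Column z-scores; constant columns map to 0 rather than NaN.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mitotraj <- function(...) stop(..., call. = FALSE)
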