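#' Calibrated 2D+t movie container
#'
#' Bundles one or two image channels (the mandatory chromatin channel and an
#' optional second channel, e.g. tubulin), the spatial/temporal calibration and
#' per-position metadata. Channels are stored as `H x W x T` numeric arrays on
#' the unsigned 16-bit intensity scale (0..65535); 8-bit inputs are upcast
#' without rescaling. All channels must share dimensions and frame count.
#'
#' @param channels named list of `H x W x T` arrays (or a single array, taken
#'   as the chromatin channel). The first channel is the chromatin channel.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param sampling_interval time between frames in minutes (> 0).
#' @param metadata named character vector of position metadata; the keys
#'   `microscope`, `experiment_id`, `plate`, `position`, `treatment` are
#'   conventional but arbitrary keys are kept.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(channels, pixel_size = 0.65, sampling_interval = 3,
                        metadata = character()) {
  if (is.array(channels) && length(dim(channels)) == 3L)
    channels <- list(chromatin = channels)
  if (!is.list(channels) || length(channels) < 1L || length(channels) > 2L)
    stop_mitotraj("'channels' must be a list of 1-2 H x W x T arrays")
  if (is.null(names(channels)) || any(names(channels) == ""))
    names(channels) <- c("chromatin", "second")[seq_along(channels)]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop_mitotraj("each channel must be a 3D array (H x W x T)")
  ref <- dims[[1]]
  for (i in seq_along(channels)) {
    if (!identical(dims[[i]], ref))
      stop_mitotraj("channel '", names(channels)[i],
                    "' does not match the chromatin channel dimensions (",
                    paste(dims[[i]], collapse = "x"), " vs ",
                    paste(ref, collapse = "x"), ")")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_mitotraj("'pixel_size' must be > 0")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop_mitotraj("'sampling_interval' must be > 0")
  structure(list(channels = channels,
                 pixel_size = pixel_size,
                 sampling_interval = sampling_interval,
                 frame_count = ref[3],
                 metadata = metadata),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("movie_stack: ", d[1], " x ", d[2], " px, ", d[3], " frames, ",
      length(x$channels), " channel(s) [",
      paste(names(x$channels), collapse = ", "), "]\n", sep = "")
  cat("  pixel size ", x$pixel_size, " um/px, interval ",
      x$sampling_interval, " min/frame\n", sep = "")
  if (length(x$metadata))
    cat("  metadata: ", paste(names(x$metadata), x$metadata, sep = "=",
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Get one frame of a movie channel
#'
#' @param movie a [movie_stack()].
#' @param frame 1-based frame index.
#' @param channel channel name or index.
#' @return numeric matrix (H x W).
#' @export
get_frame <- function(movie, frame, channel = 1L) {
  stopifnot(inherits(movie, "movie_stack"))
  if (frame < 1L || frame > movie$frame_count)
    stop_mitotraj("frame ", frame, " out of range 1..", movie$frame_count)
  movie$channels[[channel]][, , frame]
}

#' Import a calibrated image series from per-frame TIFF files
#'
#' Reads one or two channels of single-frame grayscale TIFF files into a
#' [movie_stack()]. Frames are ordered by natural sort of their file names
#' (numeric runs compare numerically, so `t0010` follows `t0009`). All files
#' of all channels must agree in dimensions, and the channels must have the
#' same number of frames; a mismatch is rejected naming the offending file.
#'
#' @param chromatin character vector of file paths, or a single glob pattern,
#'   for the mandatory chromatin channel.
#' @param second optional paths/glob for the second channel.
#' @param pixel_size,sampling_interval calibration, see [movie_stack()].
#' @param metadata named character vector of position metadata.
#' @return a [movie_stack()].
#' @export
import_image_series <- function(chromatin, second = NULL, pixel_size = 0.65,
                                sampling_interval = 3, metadata = character()) {
  expand <- function(x) {
    if (length(x) == 1L && !file.exists(x)) {
      hits <- Sys.glob(x)
      if (length(hits) == 0L) stop_mitotraj("no files match '", x, "'")
      x <- hits
    }
    x[natural_order(basename(x))]
  }
  read_channel <- function(paths) {
    frames <- vector("list", length(paths))
    ref <- NULL
    for (i in seq_along(paths)) {
      if (!file.exists(paths[i])) stop_mitotraj("file not found: ", paths[i])
      img <- tiff::readTIFF(paths[i], as.is = TRUE)
      if (length(dim(img)) == 3L) img <- img[, , 1]   # drop extra samples
      img <- unclass(img) * 1.0
      if (is.null(ref)) ref <- dim(img)
      if (!identical(dim(img), ref))
        stop_mitotraj("image dimensions of '", paths[i], "' (",
                      paste(dim(img), collapse = "x"),
                      ") differ from the first frame (",
                      paste(ref, collapse = "x"), ")")
      frames[[i]] <- img
    }
    array(unlist(frames, use.names = FALSE), dim = c(ref, length(paths)))
  }
  chromatin <- expand(chromatin)
  if (length(chromatin) < 1L) stop_mitotraj("need at least one frame")
  chans <- list(chromatin = read_channel(chromatin))
  if (!is.null(second)) {
    second <- expand(second)
    if (length(second) != length(chromatin))
      stop_mitotraj("channel frame counts differ: chromatin has ",
                    length(chromatin), " frames, second channel has ",
                    length(second), " (last file: ",
                    basename(second[length(second)]), ")")
    sec <- read_channel(second)
    if (!identical(dim(sec)[1:2], dim(chans$chromatin)[1:2]))
      stop_mitotraj("second-channel dimensions differ from chromatin channel (",
                    basename(second[1]), ")")
    chans$second <- sec
  }
  movie_stack(chans, pixel_size = pixel_size,
              sampling_interval = sampling_interval, metadata = metadata)
}
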