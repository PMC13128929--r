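#' Multi-channel flatmount image container
#'
#' Bundles the co-registered channel rasters of one flatmount (DAPI, CD31,
#' TUNEL, nuclear/membrane markers, ...) with the physical pixel size. All
#' rasters must share dimensions; intensities are arbitrary non-negative
#' units. Rasters are stored as base matrices indexed `[row, col]`, 0-based
#' pixel-center coordinates are used in all derived tables.
#'
#' @param channels named list of numeric matrices, identical dimensions.
#' @param pixel_size physical pixel size in micrometres per pixel (isotropic).
#' @param metadata optional free-form list of acquisition descriptors.
#'
#' @return An object of class `flatmount_image`.
#' @export
#' @examples
#' img <- flatmount_image(list(DAPI = matrix(0, 8, 8)), pixel_size = 0.5)
#' channel_names(img)
flatmount_image <- function(channels, pixel_size, metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1)
  nms <- names(channels)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("`channels` must be a uniquely named list of matrices", call. = FALSE)
  }
  dims <- vapply(channels, function(m) {
    if (!is.matrix(m) || !is.numeric(m)) {
      stop("every channel must be a numeric matrix", call. = FALSE)
    }
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("channel intensities must be finite and non-negative", call. = FALSE)
    }
    dim(m)
  }, integer(2))
  if (ncol(dims) > 1 && any(dims[, -1, drop = FALSE] != dims[, 1])) {
    stop("all channel rasters must share identical dimensions", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  }
  structure(
    list(channels = channels, pixel_size = as.numeric(pixel_size),
         metadata = metadata),
    class = "flatmount_image"
  )
}

#' @export
print.flatmount_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<flatmount_image> %d x %d px @ %.3g um/px\n", d[1], d[2],
              x$pixel_size))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname flatmount_image
#' @param image a `flatmount_image`.
#' @export
channel_names <- function(image) {
  stopifnot(inherits(image, "flatmount_image"))
  names(image$channels)
}

# Fetch one channel matrix, with a uniform error for unknown names.
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "flatmount_image"))
  if (!is.character(channel) || length(channel) != 1 ||
      !channel %in% names(image$channels)) {
    stop(sprintf("unknown channel '%s'; available: %s",
                 as.character(channel)[1],
                 paste(names(image$channels), collapse = ", ")),
         call. = FALSE)
  }
  image$channels[[channel]]
}

#' Read a multi-channel flatmount TIFF
#'
#' Reads a (OME-)TIFF stack with one greyscale frame per channel and maps
#' frame indices to semantic channel names. The channel map can be given as
#' a named integer vector or as a YAML/JSON config file with fields
#' `pixel_size` and `channels` (name -> 1-based frame index).
#'
#' @param path path to the TIFF file.
#' @param channel_map named integer vector (name -> frame index), or `NULL`
#'   when `config` is given.
#' @param pixel_size micrometres per pixel; ignored when `config` is given.
#' @param config optional path to a YAML (or JSON) file carrying
#'   `pixel_size` and `channels`.
#' @return a [flatmount_image].
#' @export
read_flatmount <- function(path, channel_map = NULL, pixel_size = NULL,
                           config = NULL) {
  if (!is.null(config)) {
    cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading a YAML config requires the 'yaml' package", call. = FALSE)
      }
      yaml::read_yaml(config)
    }
    pixel_size <- cfg$pixel_size
    channel_map <- unlist(cfg$channels)
  }
  stopifnot(!is.null(channel_map), !is.null(pixel_size))
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1L))
  n_frames <- dim(arr)[3]
  if (any(channel_map < 1 | channel_map > n_frames)) {
    stop(sprintf("channel map indices must be in 1..%d", n_frames),
         call. = FALSE)
  }
  # EBImage stores x (column) as the first index; transpose to [row, col]
  channels <- lapply(channel_map, function(i) t(arr[, , i]))
  flatmount_image(channels, pixel_size = pixel_size,
                  metadata = list(source = path))
}

#' Write a flatmount image as a multi-frame TIFF
#'
#' Frames are written in channel order and scaled jointly to `[0, 1]` so
#' relative intensities across channels are preserved.
#'
#' @param image a [flatmount_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flatmount <- function(image, path) {
  stopifnot(inherits(image, "flatmount_image"))
  hi <- max(1, vapply(image$channels, max, numeric(1)))
  arr <- simplify2array(lapply(image$channels, function(m) t(m) / hi))
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff")
  invisible(path)
}
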