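# Reading/writing multi-page TIFF stacks and the in-memory ImageStack
# representation every downstream module consumes.

#' Construct an ImageStack
#'
#' The canonical in-memory container for a single-channel time-lapse movie:
#' a `H x W x T` array of non-negative intensities (arbitrary camera units)
#' plus the two pieces of acquisition metadata everything downstream needs,
#' the frame interval in seconds and the pixel size in micrometers. Metadata
#' is supplied explicitly (typically from a config file), never parsed from
#' vendor TIFF tags.
#'
#' Frames are stored along the third array dimension in time order; frame `t`
#' (0-based) is `pixels[, , t + 1]`. Spatial coordinates throughout the
#' package are 0-based with `x` = column, `y` = row and pixel centers at
#' integer coordinates.
#'
#' @param pixels numeric/integer array `H x W x T`, or a matrix for a
#'   single-frame stack. All values must be finite and non-negative.
#' @param frame_interval_s time between consecutive frames, seconds (> 0).
#' @param pixel_size_um physical pixel size, micrometers (> 0).
#' @param channel_label free-text channel description.
#' @return an object of class `ImageStack` with fields `pixels`,
#'   `frame_interval_s`, `pixel_size_um`, `channel_label`.
#' @examples
#' st <- image_stack(array(0L, c(16, 16, 5)), frame_interval_s = 0.15,
#'                   pixel_size_um = 0.1)
#' n_frames(st)
#' @export
image_stack <- function(pixels, frame_interval_s, pixel_size_um,
                        channel_label = "") {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("pixels must be an H x W x T array (or a single-frame matrix)")
  }
  if (dim(pixels)[3] < 1L) stop("empty stack: at least one frame required")
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and non-negative")
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0) {
    stop("frame_interval_s must be a single positive number")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(pixels = pixels, frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um, channel_label = channel_label),
    class = "ImageStack"
  )
}

#' @rdname image_stack
#' @param x an `ImageStack`.
#' @export
n_frames <- function(x) dim(x$pixels)[3]

#' @rdname image_stack
#' @export
stack_dim <- function(x) dim(x$pixels)

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "ImageStack: %d frame(s) of %d x %d px; dt = %g s; %g um/px%s\n",
    d[3], d[1], d[2], x$frame_interval_s, x$pixel_size_um,
    if (nzchar(x$channel_label)) paste0("; channel '", x$channel_label, "'") else ""
  ))
  invisible(x)
}

#' Read a multi-page TIFF time-lapse stack
#'
#' Pages are taken in file order as time order. Integer TIFFs (8/16-bit) are
#' read losslessly; 32-bit float TIFFs written by [write_stack()] are
#' rescaled using the scale sidecar that function records.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param frame_interval_s,pixel_size_um acquisition metadata (seconds and
#'   micrometers, both > 0); supplied by the caller, not parsed from tags.
#' @param channel_label optional channel label.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, frame_interval_s, pixel_size_um,
                       channel_label = "") {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF: file contains no pages")
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  if (bits %in% c(8L, 16L)) {
    # integer samples: reread losslessly as integers
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("only single-channel grayscale TIFFs are supported")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("nonuniform page shapes in TIFF: all frames must share H x W")
  }
  px <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) px[, , t] <- pages[[t]]
  if (all(vapply(pages, is.integer, logical(1)))) {
    storage.mode(px) <- "integer"
  } else {
    scale_file <- paste0(path, ".scale.json")
    if (file.exists(scale_file)) {
      sc <- jsonlite::read_json(scale_file)$scale
      px <- px * as.numeric(sc)
    }
  }
  image_stack(px, frame_interval_s, pixel_size_um, channel_label)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Integer stacks are written as 16-bit (8-bit if all values fit) and
#' round-trip bit-identically through [read_stack()]. Float stacks are
#' written as 32-bit float after division by a power-of-two scale factor
#' chosen so values fall in \[0, 1\]; the scale is recorded in a
#' `<path>.scale.json` sidecar (power-of-two scaling preserves the float
#' mantissa, so only float32 quantisation is incurred).
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  px <- stack$pixels
  pages <- lapply(seq_len(dim(px)[3]), function(t) px[, , t])
  if (is.integer(px)) {
    mx <- max(px)
    if (mx > 65535L) stop("integer stack exceeds 16-bit range")
    bits <- if (mx <= 255L) 8L else 16L
    denom <- 2^bits - 1
    pages <- lapply(pages, function(m) m / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  } else {
    mx <- max(px)
    scale <- if (mx <= 1) 1 else 2^ceiling(log2(mx))
    pages <- lapply(pages, function(m) m / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    jsonlite::write_json(list(scale = scale), paste0(path, ".scale.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read acquisition metadata from a YAML/JSON config file
#'
#' Convenience reader for the key-value config that supplies
#' `frame_interval_s`, `pixel_size_um` and channel labels. The frame interval
#' and pixel size are deliberately taken from configuration rather than from
#' vendor TIFF tags, mirroring manual scale setting during acquisition.
#'
#' @param path YAML (or JSON, which YAML parses) config file.
#' @return named list of config values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}
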