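#' Frame stacks
#'
#' A `frame_stack` is an ordered set of equally sized grayscale frames
#' (gray levels 0-255) with a frame rate and an optional physical pixel
#' size. It is the container produced by the simulators and consumed by
#' the segmentation and shape-metric functions.
#'
#' @param frames A numeric `nr x nc x n_frames` array, or a list of
#'   equally sized matrices.
#' @param frame_rate_hz Frames per second.
#' @param pixel_size Physical pixel edge length (micrometers per pixel;
#'   default 1, i.e. areas are reported in px^2).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, pixel_size = 1) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must have the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3, frame_rate_hz > 0,
            pixel_size > 0)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size = pixel_size),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %g Hz (%g um/px)\n",
              d[3], d[1], d[2], x$frame_rate_hz, x$pixel_size))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) dim(x$frames)[3]

get_frame <- function(stack, i) stack$frames[, , i]

frame_times <- function(stack) {
  (seq_len(length(stack)) - 1) / stack$frame_rate_hz
}

#' Read and write frame stacks as multi-page TIFF
#'
#' `write_frame_stack()` stores the stack as an 8-bit grayscale
#' multi-page TIFF; `read_frame_stack()` reads one back. Reading errors
#' name the offending file.
#'
#' @param stack A [frame_stack()].
#' @param path Path to a `.tif`/`.tiff` file.
#' @param frame_rate_hz,pixel_size Acquisition metadata for the stack
#'   being read (TIFF does not carry them portably).
#' @return `read_frame_stack()` returns a [frame_stack()];
#'   `write_frame_stack()` returns `path` invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack)
  pages <- lapply(seq_len(n), function(i) get_frame(stack, i) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, frame_rate_hz = 10, pixel_size = 1) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop("failed to read frame stack from '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1] # collapse any channels
    round(p * 255)
  })
  frame_stack(pages, frame_rate_hz = frame_rate_hz, pixel_size = pixel_size)
}
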