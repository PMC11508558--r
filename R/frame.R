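#' Image frame
#'
#' A single 2D intensity frame.  For conventional video imagers both axes
#' are spatial; for a pushbroom hyperspectral imager the instantaneous
#' frame has one spatial and one spectral axis.  By convention the first
#' (row) index is the spatial axis of a hyperspectral frame, so all
#' direction-selective focus measures difference along rows.
#'
#' @param pixels numeric matrix of non-negative detector counts
#'   (rows = height H, columns = width W).
#' @param bit_depth sensor bit depth (12, 14 or 16); intensities must lie
#'   in `[0, 2^bit_depth - 1]`.
#' @param axes `"spatial_spatial"` (video) or `"spatial_spectral"`
#'   (pushbroom hyperspectral, rows = spatial).
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(pixels, bit_depth = 12L,
                        axes = c("spatial_spatial", "spatial_spectral")) {
  axes <- match.arg(axes)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("frame must be at least 3x3 (smallest kernels are 3x3)", call. = FALSE)
  if (!bit_depth %in% c(12L, 14L, 16L))
    stop("`bit_depth` must be 12, 14 or 16", call. = FALSE)
  if (any(pixels < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (any(pixels > 2^bit_depth - 1))
    stop("intensities exceed 2^bit_depth - 1", call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 axes = axes),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d, %d-bit, axes=%s, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$axes,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

as_pixel_matrix <- function(frame) {
  if (inherits(frame, "image_frame")) frame$pixels
  else if (is.matrix(frame)) frame
  else stop("expected an image_frame or a matrix", call. = FALSE)
}

#' Through-focus stack
#'
#' An ordered series of frames of one field of view captured at strictly
#' increasing focal positions, optionally paired with a dark frame
#' captured before the series acquisition.
#'
#' @param frames list of [image_frame] objects sharing shape, axes and
#'   bit depth.
#' @param z_um numeric vector of focal positions in micrometres, strictly
#'   increasing, one per frame.
#' @param dark_frame optional [image_frame] with the same shape.
#' @param meta named list of provenance metadata (free-form; the synthetic
#'   generator records the true focus index here).
#' @return an object of class `focus_stack`.
#' @export
focus_stack <- function(frames, z_um, dark_frame = NULL, meta = list()) {
  if (!length(frames)) stop("a stack needs at least one frame", call. = FALSE)
  frames <- lapply(frames, function(f)
    if (inherits(f, "image_frame")) f else image_frame(f))
  if (length(z_um) != length(frames))
    stop("length(z_um) must equal the number of frames", call. = FALSE)
  if (any(diff(z_um) <= 0))
    stop("z positions must be strictly increasing", call. = FALSE)
  d1 <- dim(frames[[1L]]$pixels)
  same <- vapply(frames, function(f)
    identical(dim(f$pixels), d1) &&
      identical(f$axes, frames[[1L]]$axes) &&
      identical(f$bit_depth, frames[[1L]]$bit_depth), logical(1))
  if (!all(same))
    stop("all frames must share shape, axes and bit depth", call. = FALSE)
  if (!is.null(dark_frame)) {
    if (!inherits(dark_frame, "image_frame")) dark_frame <- image_frame(dark_frame)
    if (!identical(dim(dark_frame$pixels), d1))
      stop("dark frame shape differs from stack frames", call. = FALSE)
  }
  structure(list(frames = frames, z_um = as.numeric(z_um),
                 dark_frame = dark_frame, meta = meta),
            class = "focus_stack")
}

#' @export
print.focus_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]]$pixels)
  cat(sprintf("<focus_stack> %d frames of %d x %d (%d-bit, %s), z %g..%g um%s\n",
              length(x$frames), d[1], d[2], x$frames[[1L]]$bit_depth,
              x$frames[[1L]]$axes, min(x$z_um), max(x$z_um),
              if (is.null(x$dark_frame)) "" else ", dark frame attached"))
  invisible(x)
}

#' @export
length.focus_stack <- function(x) length(x$frames)

#' Region-of-interest specification
#'
#' Sub-sampling window applied identically to every frame of a stack.
#' Offsets are 0-based (the first pixel is `row_offset = 0`,
#' `col_offset = 0`).
#'
#' @param row_offset,col_offset 0-based offsets of the window origin.
#' @param rows,cols window extent in pixels (each at least 3).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(row_offset, col_offset, rows, cols) {
  v <- c(row_offset, col_offset, rows, cols)
  if (any(v != round(v)) || row_offset < 0 || col_offset < 0)
    stop("ROI offsets must be non-negative integers", call. = FALSE)
  if (rows < 3 || cols < 3)
    stop("ROI must be at least 3x3", call. = FALSE)
  structure(list(row_offset = as.integer(row_offset),
                 col_offset = as.integer(col_offset),
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "roi_spec")
}

#' Subtract the paired dark frame from every frame
#'
#' Removes the fixed-pattern detector offset recorded before the series
#' acquisition.  Differences are clamped at zero: counts are non-negative.
#' If the stack carries no dark frame the stack is returned unchanged with
#' a warning.
#'
#' @param stack a [focus_stack].
#' @return a new [focus_stack] with dark-corrected frames and the dark
#'   frame cleared.
#' @export
subtract_dark <- function(stack) {
  stopifnot(inherits(stack, "focus_stack"))
  if (is.null(stack$dark_frame)) {
    warning("stack has no dark frame; returning it unchanged")
    return(stack)
  }
  d <- stack$dark_frame$pixels
  frames <- lapply(stack$frames, function(f) {
    f$pixels <- pmax(f$pixels - d, 0)
    f
  })
  meta <- stack$meta
  meta$dark_subtracted <- TRUE
  focus_stack(frames, stack$z_um, dark_frame = NULL, meta = meta)
}

#' Crop every frame of a stack to a region of interest
#'
#' ROI sub-sampling reduces noise sensitivity and computation; it is
#' applied identically to each frame (and to the dark frame, if present)
#' so z positions are preserved.
#'
#' @param stack a [focus_stack].
#' @param roi a [roi_spec].
#' @return the cropped [focus_stack].
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "focus_stack"), inherits(roi, "roi_spec"))
  d <- dim(stack$frames[[1L]]$pixels)
  ri <- roi$row_offset + seq_len(roi$rows)
  ci <- roi$col_offset + seq_len(roi$cols)
  if (max(ri) > d[1] || max(ci) > d[2])
    stop("ROI extends outside the frame", call. = FALSE)
  frames <- lapply(stack$frames, function(f) {
    f$pixels <- f$pixels[ri, ci, drop = FALSE]
    f
  })
  dark <- stack$dark_frame
  if (!is.null(dark)) dark$pixels <- dark$pixels[ri, ci, drop = FALSE]
  focus_stack(frames, stack$z_um, dark_frame = dark, meta = stack$meta)
}
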