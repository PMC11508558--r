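# Stack I/O: ENVI BIL raw+header pairs (the de-facto pushbroom container)
# and multi-page TIFF, each with a JSON sidecar manifest holding the focal
# positions, axis semantics, bit depth and an optional dark-frame path.

manifest_path <- function(path) paste0(path, ".json")

write_manifest <- function(path, stack, format) {
  m <- list(format = format,
            z_um = stack$z_um,
            axes = stack$frames[[1L]]$axes,
            bit_depth = stack$frames[[1L]]$bit_depth)
  if (!is.null(stack$dark_frame)) m$dark <- basename(dark_path(path, format))
  jsonlite::write_json(m, manifest_path(path), auto_unbox = TRUE, digits = NA)
}

dark_path <- function(path, format) {
  base <- sub("\\.(raw|tif|tiff)$", "", path)
  paste0(base, "_dark.", if (format == "envi") "raw" else "tif")
}

# -- ENVI BIL ----------------------------------------------------------------
# Cube layout: lines = frames, samples = frame columns (W), bands = frame
# rows (H).  BIL interleave stores, for each line, band after band, i.e.
# each frame row-major.  uint16 little-endian (ENVI data type 12).

write_envi_pair <- function(pixels_list, path, bit_depth) {
  hdr <- sub("\\.raw$", ".hdr", path)
  d <- dim(pixels_list[[1L]])
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in pixels_list) {
    v <- as.integer(round(t(p)))   # row-major within a line
    writeBin(v, con, size = 2L, endian = "little")
  }
  writeLines(c("ENVI",
               "description = {through-focus stack}",
               sprintf("samples = %d", d[2]),
               sprintf("lines = %d", length(pixels_list)),
               sprintf("bands = %d", d[1]),
               "header offset = 0",
               "file type = ENVI Standard",
               "data type = 12",
               "interleave = bil",
               "byte order = 0",
               sprintf("hsfocus bit depth = %d", bit_depth)),
             hdr)
}

read_envi_header <- function(hdr) {
  ln <- readLines(hdr, warn = FALSE)
  if (!length(ln) || !grepl("^ENVI", ln[1]))
    stop("not an ENVI header: ", hdr, call. = FALSE)
  get <- function(key, required = TRUE) {
    hit <- grep(paste0("^", key, "\\s*="), ln, value = TRUE)
    if (!length(hit)) {
      if (required) stop("ENVI header missing field: ", key, call. = FALSE)
      return(NULL)
    }
    trimws(sub(".*=", "", hit[1]))
  }
  list(samples = as.integer(get("samples")),
       lines = as.integer(get("lines")),
       bands = as.integer(get("bands")),
       data_type = as.integer(get("data type")),
       interleave = tolower(get("interleave")),
       byte_order = as.integer(get("byte order")))
}

read_envi_pair <- function(path) {
  hdr <- sub("\\.raw$", ".hdr", path)
  if (!file.exists(hdr)) stop("missing ENVI header: ", hdr, call. = FALSE)
  h <- read_envi_header(hdr)
  if (h$data_type != 12L || h$interleave != "bil")
    stop("unsupported ENVI layout (expect uint16 BIL)", call. = FALSE)
  n <- h$samples * h$lines * h$bands
  v <- readBin(path, "integer", n = n, size = 2L, signed = FALSE,
               endian = if (h$byte_order == 0L) "little" else "big")
  if (length(v) != n) stop("ENVI raw file truncated", call. = FALSE)
  lapply(seq_len(h$lines), function(s) {
    off <- (s - 1L) * h$samples * h$bands
    matrix(as.double(v[off + seq_len(h$samples * h$bands)]),
           nrow = h$bands, ncol = h$samples, byrow = TRUE)
  })
}

# -- multi-page TIFF ---------------------------------------------------------
# Stored as 16-bit grayscale; integer counts c are written as c/65535 so
# the round trip is exact for any value representable at the sensor depth.

write_tiff_stack <- function(pixels_list, path) {
  imgs <- lapply(pixels_list, function(p) round(p) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
}

read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) round(m * 65535))
}

#' Write a through-focus stack to disk
#'
#' Writes either an ENVI BIL raw/header pair (`format = "envi"`,
#' `path` ending in `.raw`) or a multi-page 16-bit TIFF
#' (`format = "tiff"`), plus a JSON manifest `<path>.json` carrying the
#' focal positions, axes tag, bit depth and dark-frame pointer.  Pixel
#' values are rounded to integer counts on write.
#'
#' @param stack a [focus_stack].
#' @param path output file path (`.raw` or `.tif`).
#' @param format `"envi"` or `"tiff"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "envi", "tiff")) {
  stopifnot(inherits(stack, "focus_stack"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.raw$", path)) "envi" else "tiff"
  pix <- lapply(stack$frames, `[[`, "pixels")
  bd <- stack$frames[[1L]]$bit_depth
  if (format == "envi") write_envi_pair(pix, path, bd)
  else write_tiff_stack(pix, path)
  if (!is.null(stack$dark_frame)) {
    dp <- dark_path(path, format)
    if (format == "envi") write_envi_pair(list(stack$dark_frame$pixels), dp, bd)
    else write_tiff_stack(list(stack$dark_frame$pixels), dp)
  }
  write_manifest(path, stack, format)
  invisible(path)
}

#' Read a through-focus stack from disk
#'
#' Accepts an ENVI raw/header pair, a multi-page TIFF (both with the JSON
#' manifest written by [write_stack()]), or a directory of single-frame
#' files with a `manifest.json` listing `files` and `z_um`; directory
#' frames are re-ordered by ascending z regardless of filename order.
#'
#' @param path stack file or directory.
#' @param format_hint optional `"envi"`, `"tiff"` or `"dir"` override.
#' @return a [focus_stack].
#' @export
read_stack <- function(path, format_hint = NULL) {
  format <- format_hint
  if (is.null(format)) {
    format <- if (dir.exists(path)) "dir"
    else if (grepl("\\.raw$", path)) "envi"
    else "tiff"
  }
  if (format == "dir") return(read_stack_dir(path))
  mf <- manifest_path(path)
  if (!file.exists(mf)) stop("missing stack manifest: ", mf, call. = FALSE)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  pix <- if (format == "envi") read_envi_pair(path) else read_tiff_stack(path)
  z <- as.numeric(m$z_um)
  if (length(z) != length(pix))
    stop("manifest z positions do not match frame count", call. = FALSE)
  if (any(diff(z) <= 0))
    stop("manifest z positions are not strictly increasing", call. = FALSE)
  bd <- as.integer(m$bit_depth)
  axes <- m$axes
  frames <- lapply(pix, image_frame, bit_depth = bd, axes = axes)
  dark <- NULL
  if (!is.null(m$dark)) {
    dp <- file.path(dirname(path), m$dark)
    dpx <- if (format == "envi") read_envi_pair(dp) else read_tiff_stack(dp)
    dark <- image_frame(dpx[[1L]], bit_depth = bd, axes = axes)
  }
  focus_stack(frames, z, dark_frame = dark)
}

read_stack_dir <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing stack manifest: ", mf, call. = FALSE)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(m$files) || is.null(m$z_um) || length(m$files) != length(m$z_um))
    stop("directory manifest must pair `files` with `z_um`", call. = FALSE)
  ord <- order(as.numeric(m$z_um))
  z <- as.numeric(m$z_um)[ord]
  if (any(diff(z) <= 0))
    stop("manifest z positions are not strictly increasing", call. = FALSE)
  bd <- if (is.null(m$bit_depth)) 12L else as.integer(m$bit_depth)
  axes <- if (is.null(m$axes)) "spatial_spatial" else m$axes
  frames <- lapply(m$files[ord], function(f) {
    fp <- file.path(path, f)
    pix <- if (grepl("\\.raw$", fp)) read_envi_pair(fp)[[1L]]
    else read_tiff_stack(fp)[[1L]]
    image_frame(pix, bit_depth = bd, axes = axes)
  })
  focus_stack(frames, z)
}
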