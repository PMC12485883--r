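#' Channel image container
#'
#' A single-channel 2D grayscale image together with its physical pixel size
#' and a channel label. Pixels are stored as a numeric matrix (rows x cols).
#' All public pixel coordinates in this package are 0-based, with the center
#' of pixel \code{(i, j)} at the continuous position \code{(i, j)}.
#'
#' @param pixels numeric matrix of intensities (rows x cols), all finite.
#' @param pixel_size_nm positive physical pixel edge length in nanometers
#'   (83.3 for the epi-fluorescence setup, 25 for STED).
#' @param channel_label short channel name, e.g. \code{"GFP"} or \code{"red"}.
#' @return An object of class \code{channel_image}.
#' @examples
#' img <- channel_image(matrix(rpois(64 * 64, 50), 64, 64), 83.3, "GFP")
#' dim(img)
#' @export
channel_image <- function(pixels, pixel_size_nm, channel_label = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("'pixels' must be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a single positive number")
  structure(
    list(pixels = pixels,
         pixel_size_nm = as.numeric(pixel_size_nm),
         channel_label = as.character(channel_label)),
    class = "channel_image")
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_image '%s'> %d x %d px @ %g nm/px, range [%g, %g]\n",
              x$channel_label, d[1], d[2], x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_channel_image <- function(x, pixel_size_nm = NULL, channel_label = NULL) {
  if (inherits(x, "channel_image")) {
    if (!is.null(pixel_size_nm)) x$pixel_size_nm <- pixel_size_nm
    if (!is.null(channel_label)) x$channel_label <- channel_label
    return(x)
  }
  channel_image(x, if (is.null(pixel_size_nm)) 1 else pixel_size_nm,
                if (is.null(channel_label)) "" else channel_label)
}

# Raw pixel matrix from a channel_image or plain matrix.
img_pixels <- function(x) {
  if (inherits(x, "channel_image")) x$pixels else as.matrix(x)
}

#' Square region of interest
#'
#' An axis-aligned square analysis window in 0-based, half-open pixel
#' coordinates: the ROI covers pixel rows \code{row0 .. row0 + side_px - 1}
#' and likewise for columns.
#'
#' @param row0,col0 0-based integer top-left corner.
#' @param side_px positive integer edge length in pixels.
#' @return An object of class \code{square_roi}.
#' @examples
#' square_roi(10, 10, 64)
#' @export
square_roi <- function(row0, col0, side_px) {
  if (any(row0 < 0, col0 < 0) || row0 != round(row0) || col0 != round(col0))
    stop("'row0' and 'col0' must be non-negative integers")
  if (side_px < 1 || side_px != round(side_px))
    stop("'side_px' must be a positive integer")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 side_px = as.integer(side_px)),
            class = "square_roi")
}

#' @export
print.square_roi <- function(x, ...) {
  cat(sprintf("<square_roi> top-left (%d, %d), side %d px\n",
              x$row0, x$col0, x$side_px))
  invisible(x)
}

# Check that an ROI fits entirely inside an image; error if not.
check_roi_inside <- function(roi, image, what = "ROI") {
  d <- dim(img_pixels(image))
  if (roi$row0 + roi$side_px > d[1] || roi$col0 + roi$side_px > d[2])
    stop(sprintf(
      "%s [rows %d..%d, cols %d..%d] does not fit inside the %d x %d image",
      what, roi$row0, roi$row0 + roi$side_px - 1L,
      roi$col0, roi$col0 + roi$side_px - 1L, d[1], d[2]))
  invisible(TRUE)
}

# Extract the ROI sub-matrix (1-based internally).
roi_pixels <- function(image, roi) {
  px <- img_pixels(image)
  check_roi_inside(roi, px)
  px[(roi$row0 + 1L):(roi$row0 + roi$side_px),
     (roi$col0 + 1L):(roi$col0 + roi$side_px), drop = FALSE]
}

#' Read a single-channel grayscale TIFF
#'
#' Reads a grayscale TIFF as stored integer (or float) intensity values,
#' without rescaling to \code{[0, 1]}.
#'
#' @param path path to the TIFF file.
#' @inheritParams channel_image
#' @return A \code{channel_image}.
#' @export
read_channel_tiff <- function(path, pixel_size_nm, channel_label = "") {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  channel_image(m, pixel_size_nm, channel_label)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' Intensities are rounded and clipped to the 16-bit range \code{[0, 65535]}.
#'
#' @param image a \code{channel_image} or numeric matrix.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  px <- img_pixels(image)
  px <- pmin(pmax(round(px), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
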