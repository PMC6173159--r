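## Image containers and I/O.
##
## Rasters are stored as base arrays of integers in 0..255:
##   colour image: array(dim = c(height, width, 3))  (R, G, B planes)
##   greyscale:    matrix(nrow = height, ncol = width)
## Row index = y (increasing downward), column index = x. Public rectangle
## coordinates are 0-based and half-open, matching common image tooling;
## conversion to R's 1-based indices happens here and nowhere else.

#' Analysis rectangle
#'
#' The manually defined torso region within which spots are measured. All
#' lengths downstream are expressed in giraffe units (GU), where 1 GU is the
#' height of this rectangle, so measurements are approximately invariant to
#' image resolution and animal size.
#'
#' @param x0,y0,x1,y1 Pixel coordinates, 0-based, half-open (`x1`/`y1`
#'   exclusive). y increases downward.
#' @return An object of class `analysis_rect` with fields `x0,y0,x1,y1` and
#'   `height_px = y1 - y0`.
#' @examples
#' r <- analysis_rect(10, 20, 110, 100)
#' r$height_px  # 80
#' @export
analysis_rect <- function(x0, y0, x1, y1) {
  for (v in c("x0", "y0", "x1", "y1"))
    stop_if_not_scalar_num(get(v), v, integer = TRUE)
  if (x1 <= x0) stop("analysis rectangle must have x1 > x0")
  if (y1 <= y0) stop("analysis rectangle must have y1 > y0")
  if (y1 - y0 < 64)
    warning("analysis rectangle is under 64 px tall; GU measurements will be coarse")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1),
                 height_px = as.integer(y1 - y0)),
            class = "analysis_rect")
}

#' @export
print.analysis_rect <- function(x, ...) {
  cat(sprintf("Analysis rectangle [%d,%d) x [%d,%d), height %d px (1 GU = %d px)\n",
              x$x0, x$x1, x$y0, x$y1, x$height_px, x$height_px))
  invisible(x)
}

as_uint8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Read a coat photograph
#'
#' Reads an 8-bit PNG or TIFF image into an integer RGB array (values 0-255).
#' Greyscale files are expanded to three identical channels; alpha channels
#' are dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer array `height x width x 3`.
#' @export
read_coat_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = stop("JPEG input is not supported; convert to PNG or TIFF first"),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] >= 4L) img <- img[, , 1:3, drop = FALSE]
  as_uint8(img * 255)
}

#' Write an RGB raster as 8-bit PNG
#'
#' @param image Integer array `h x w x 3` with values 0-255.
#' @param path Output path.
#' @export
write_coat_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  png::writePNG(array(image / 255, dim(image)), path)
  invisible(path)
}

## Validate a colour raster.
check_rgb8 <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("expected a height x width x 3 RGB array")
  if (!is.numeric(image) || any(image < 0) || any(image > 255) ||
      any(image != round(image)))
    stop("expected 8-bit channel values (integers 0-255)")
  invisible(image)
}
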