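#' Create a blank RGB raster
#'
#' Rasters throughout the package are plain `h x w x 3` arrays of 8-bit
#' channel values in `[0, 255]`.  Pixel coordinates are 0-based, row-major,
#' half-open wherever boxes are involved, so that tile origins and centroids
#' compose without off-by-one bookkeeping.
#'
#' @param h,w positive integer dimensions in pixels.
#' @param fill length-3 RGB fill colour (default white, the unstained
#'   background of an HE slide scan).
#' @return an `h x w x 3` numeric array.
#' @export
new_raster <- function(h, w, fill = c(255, 255, 255)) {
  stopifnot(h >= 0, w >= 0, length(fill) == 3)
  array(rep(fill, each = h * w), dim = c(h, w, 3))
}

#' Validate an RGB raster
#' @param x object to check.
#' @return `x`, invisibly; stops on malformed input.
#' @keywords internal
check_raster <- function(x) {
  if (!(is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3))
    stop("raster must be an h x w x 3 array", call. = FALSE)
  if (any(!is.finite(x)) || min(x) < 0 || max(x) > 255)
    stop("raster channel values must be finite and in [0, 255]", call. = FALSE)
  invisible(x)
}

#' Convert an RGB raster to luminance
#'
#' Rec. 601 luma weights; output is an `h x w` matrix in `[0, 255]`.
#' @param x RGB raster.
#' @return numeric matrix.
#' @export
raster_gray <- function(x) {
  check_raster(x)
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

#' Read a raster from PNG or TIFF
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return an `h x w x 3` raster with channels in `[0, 255]`.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write a raster to PNG or TIFF
#'
#' @param x RGB raster.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  check_raster(x)
  ext <- tolower(tools::file_ext(path))
  img <- x / 255
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported raster format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read / write 16-bit integer label masks
#'
#' Label masks (0 = background, positive integers = cell ids) are exchanged
#' as single-channel 16-bit TIFF, the conventional format for instance
#' segmentation ground truth.
#'
#' @param path file path (`.tif`/`.tiff` or `.png`).
#' @return `read_label_mask`: an integer matrix.
#' @export
read_label_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow = nrow(img))
}

#' @rdname read_label_mask
#' @param mask integer label matrix with values in `[0, 65535]`.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), min(mask) >= 0, max(mask) <= 65535)
  img <- mask / 65535
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported mask format: ", ext, call. = FALSE))
  invisible(path)
}
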