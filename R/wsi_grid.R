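#' Split a whole-slide raster into a fixed-size tile grid
#'
#' Whole-slide images are far too large for cell segmentation in one pass, so
#' they are cut into square tiles (default 256 px, a size chosen to fit the
#' segmentation backend rather than to matter scientifically).  The raster is
#' padded on the right and bottom with pure white -- the colour of unstained
#' background -- up to the smallest multiple of `T`, and tiles are emitted in
#' row-major order with 0-based, half-open pixel boxes.
#'
#' @param wsi RGB raster (`h x w x 3`, values 0--255).
#' @param T tile side in pixels, `>= 8`.
#' @return an object of class `tile_grid`: a list with `tile_size`,
#'   `orig_h`, `orig_w`, `padded_h`, `padded_w`, `nrow`, `ncol` and `tiles`,
#'   where each tile is `list(row, col, y0, x0, raster)` (indices and origins
#'   0-based).
#' @seealso [reassemble()]
#' @export
split_to_grid <- function(wsi, T = 256) {
  check_raster(wsi)
  if (!is.numeric(T) || length(T) != 1 || T < 8)
    stop("tile size T must be a single number >= 8", call. = FALSE)
  T <- as.integer(T)
  h <- dim(wsi)[1]; w <- dim(wsi)[2]
  ph <- as.integer(ceiling(h / T) * T)
  pw <- as.integer(ceiling(w / T) * T)
  padded <- new_raster(ph, pw, fill = c(255, 255, 255))
  padded[seq_len(h), seq_len(w), ] <- wsi
  nr <- ph %/% T; nc <- pw %/% T
  tiles <- vector("list", nr * nc)
  i <- 1L
  for (r in seq_len(nr) - 1L) {
    for (cc in seq_len(nc) - 1L) {
      y0 <- r * T; x0 <- cc * T
      tiles[[i]] <- list(row = r, col = cc, y0 = y0, x0 = x0,
                         raster = padded[y0 + seq_len(T), x0 + seq_len(T), , drop = FALSE])
      i <- i + 1L
    }
  }
  structure(list(tile_size = T, orig_h = h, orig_w = w,
                 padded_h = ph, padded_w = pw, nrow = nr, ncol = nc,
                 tiles = tiles),
            class = "tile_grid")
}

#' Reassemble tile-level outputs into a slide-sized raster
#'
#' Inverse of [split_to_grid()]: pastes one output per tile back at its
#' original coordinates and crops the padding, so
#' `reassemble(split_to_grid(x), ...)` returns `x` bit-exactly.  Outputs may
#' be RGB rasters or plain matrices (e.g. label or class maps).
#'
#' @param grid a `tile_grid`.
#' @param tile_outputs list with one `T x T` raster or matrix per tile, in
#'   the grid's row-major order.
#' @param original_h,original_w dimensions of the output; default the grid's
#'   original slide size.
#' @return an `original_h x original_w (x 3)` raster or matrix.
#' @export
reassemble <- function(grid, tile_outputs,
                       original_h = grid$orig_h, original_w = grid$orig_w) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tile_outputs) != length(grid$tiles))
    stop("expected ", length(grid$tiles), " tile outputs, got ",
         length(tile_outputs), call. = FALSE)
  T <- grid$tile_size
  if (length(tile_outputs) == 0)
    return(matrix(0, nrow = original_h, ncol = original_w)[seq_len(original_h),
                                                          seq_len(original_w), drop = FALSE])
  rgb <- length(dim(tile_outputs[[1]])) == 3
  canvas <- if (rgb) array(0, dim = c(grid$padded_h, grid$padded_w, 3))
            else matrix(0, grid$padded_h, grid$padded_w)
  for (i in seq_along(grid$tiles)) {
    out <- tile_outputs[[i]]
    d <- dim(out)
    if (d[1] != T || d[2] != T)
      stop("tile output ", i, " is not ", T, "x", T, call. = FALSE)
    t0 <- grid$tiles[[i]]
    ys <- t0$y0 + seq_len(T); xs <- t0$x0 + seq_len(T)
    if (rgb) canvas[ys, xs, ] <- out else canvas[ys, xs] <- out
  }
  if (rgb) canvas[seq_len(original_h), seq_len(original_w), , drop = FALSE]
  else canvas[seq_len(original_h), seq_len(original_w), drop = FALSE]
}

#' Detect the stained-tissue region of a slide
#'
#' The stained tissue (pink/purple on white) is located by HSV-style
#' saturation: `(max - min) / max` over the three channels, defined as 0 for
#' pure white and pure black.  Pixels above the threshold are tissue;
#' connected blobs smaller than `min_blob_px` are discarded as debris and
#' holes inside tissue are filled.  The resulting pixel count is the "stain
#' area" denominator of the cell-area rate.
#'
#' @param wsi RGB raster.
#' @param saturation_threshold saturation cut in `[0, 1]` (default 0.08).
#' @param min_blob_px minimum blob size kept, in pixels (default 64).
#' @return an object of class `tissue_mask`: `list(mask, area_px)` with a
#'   logical matrix and its true-pixel count.
#' @export
detect_tissue <- function(wsi, saturation_threshold = 0.08, min_blob_px = 64) {
  check_raster(wsi)
  if (saturation_threshold < 0 || saturation_threshold > 1)
    stop("saturation_threshold must be in [0, 1]", call. = FALSE)
  mx <- pmax(wsi[, , 1], wsi[, , 2], wsi[, , 3])
  mn <- pmin(wsi[, , 1], wsi[, , 2], wsi[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  m <- sat > saturation_threshold
  if (any(m)) {
    lab <- EBImage::bwlabel(m * 1)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = max(lab))
      keep <- which(sizes >= min_blob_px)
      m <- matrix(lab %in% keep, nrow = nrow(lab))
    }
    if (any(m)) m <- EBImage::fillHull(m * 1) > 0
  }
  structure(list(mask = m, area_px = sum(m)), class = "tissue_mask")
}

#' Export tile boxes as a data frame
#'
#' @param grid a `tile_grid`.
#' @return data frame with columns `row`, `col`, `y0`, `x0`, `T`.
#' @export
tile_boxes <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  data.frame(
    row = vapply(grid$tiles, `[[`, integer(1), "row"),
    col = vapply(grid$tiles, `[[`, integer(1), "col"),
    y0  = vapply(grid$tiles, function(t) as.integer(t$y0), integer(1)),
    x0  = vapply(grid$tiles, function(t) as.integer(t$x0), integer(1)),
    T   = grid$tile_size)
}
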