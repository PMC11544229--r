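#' Segmentation backend configuration
#'
#' The pipeline treats cell segmentation as a pluggable backend.  The
#' production choice in this field is a fine-tuned generalist neural segmenter
#' (Cellpose `cyto2`, grayscale channels `[0, 0]`, other settings default);
#' such a model is wired in through the `"custom"` backend by supplying a
#' function `f(tile) -> label matrix`.  The built-in `"classical"` backend
#' (grayscale conversion, background thresholding, distance-transform
#' watershed, minimum object scale tied to `diameter`) is fully deterministic
#' and needs no trained weights, so the whole pipeline is testable offline.
#'
#' @param backend `"classical"` or `"custom"`.
#' @param diameter expected cell diameter in pixels, or `NULL` for automatic
#'   estimation from the tile (median connected-component size).  For the
#'   classical backend this sets the minimum object scale.
#' @param channels length-2 integer channel spec, kept for parity with
#'   external backends (`c(0, 0)` = grayscale, no nucleus channel).
#' @param fun for `backend = "custom"`: a function mapping an RGB tile to an
#'   integer label matrix of the same height/width.
#' @param model_ref opaque identifier/path of an external model, or `NULL`.
#' @return an object of class `segmenter_config`.
#' @export
segmenter_config <- function(backend = "classical", diameter = NULL,
                             channels = c(0L, 0L), fun = NULL, model_ref = NULL) {
  if (!backend %in% c("classical", "custom"))
    stop("unknown segmentation backend: ", backend, call. = FALSE)
  if (!is.null(diameter) && (!is.numeric(diameter) || diameter <= 0))
    stop("diameter must be positive or NULL (auto)", call. = FALSE)
  if (backend == "custom" && !is.function(fun))
    stop("custom backend requires `fun`", call. = FALSE)
  structure(list(backend = backend, diameter = diameter,
                 channels = as.integer(channels), fun = fun,
                 model_ref = model_ref),
            class = "segmenter_config")
}

#' Run the segmentation backend on one tile
#'
#' Classical route: luminance below a background cut (white background is
#' near 255) defines foreground; the distance transform is watershed-split to
#' separate touching cells; objects smaller than the minimum area implied by
#' `diameter` are dropped.  Deterministic for fixed input and config.
#'
#' @param tile RGB raster.
#' @param config a [segmenter_config()].
#' @return integer label matrix (`0` background, `1..n` cells) of the tile's
#'   shape.
#' @export
run_backend <- function(tile, config = segmenter_config()) {
  check_raster(tile)
  if (config$backend == "custom") {
    lab <- config$fun(tile)
    stopifnot(is.matrix(lab), all(dim(lab) == dim(tile)[1:2]))
    return(relabel_sequential(matrix(as.integer(lab), nrow = nrow(lab))))
  }
  gray <- raster_gray(tile)
  # adaptive cut between the white background mode and the stain: Otsu on
  # the luminance histogram, clamped into a near-white band because the
  # background of an HE scan is controlled white while stain intensities
  # vary freely (an unclamped Otsu lands inside the stain modes)
  thr <- min(248, max(240, otsu_threshold(gray)))
  fg <- gray < thr
  if (!any(fg)) return(matrix(0L, nrow(gray), ncol(gray)))
  diam <- config$diameter
  if (is.null(diam)) {
    cc <- EBImage::bwlabel(fg * 1)
    sizes <- tabulate(cc[cc > 0])
    sizes <- sizes[sizes > 0]
    diam <- if (length(sizes)) max(5, 2 * sqrt(stats::median(sizes) / pi)) else 15
  }
  dm <- EBImage::distmap(fg * 1)
  # watershed tolerance scales with the object radius so one basin per cell
  lab <- EBImage::watershed(dm, tolerance = max(1, diam / 4), ext = 1)
  lab <- matrix(as.integer(lab), nrow = nrow(lab))
  min_area <- max(4, round(pi * (diam / 2)^2 / 4))
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes > 0 & sizes < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_sequential(lab)
}

#' Renumber mask labels to 1..n preserving order of first appearance
#' @keywords internal
relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  lab[lab > 0] <- lut[lab[lab > 0]]
  lab
}

#' Otsu threshold on a 0--255 luminance matrix
#' @keywords internal
otsu_threshold <- function(gray) {
  h <- tabulate(pmin(255L, pmax(0L, as.integer(floor(gray)))) + 1L, nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1
}

#' Extract per-cell objects from a label mask
#'
#' One object per positive label.  Coordinates are 0-based; `tile_origin`
#' (the tile's `(y0, x0)` in slide coordinates) is added so objects from
#' different tiles live in one slide frame.  The centroid is the arithmetic
#' mean of the label's pixel coordinates; the contour is the ordered outer
#' boundary (traced with `EBImage::ocontour`).
#'
#' @param mask integer label matrix.
#' @param tile_origin numeric `(y0, x0)` offset, default `c(0, 0)`.
#' @return list of `cell_object`s: `list(cell_id, centroid, area_px, bbox,
#'   contour, tile_origin)` with `bbox = (y0, x0, y1, x1)` half-open.
#' @export
extract_cells <- function(mask, tile_origin = c(0, 0)) {
  stopifnot(is.matrix(mask))
  ids <- sort(unique(mask[mask > 0]))
  if (!length(ids)) return(list())
  contours <- EBImage::ocontour(EBImage::Image(mask))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    px <- which(mask == id, arr.ind = TRUE) - 1  # 0-based (row, col)
    ctr <- colMeans(px) + tile_origin
    bb <- c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1, max(px[, 2]) + 1) +
      c(tile_origin, tile_origin)
    contour <- contours[[as.character(id)]]
    if (is.null(contour) && length(contours) >= i) contour <- contours[[i]]
    if (!is.null(contour))
      contour <- sweep(contour[, c(1, 2), drop = FALSE], 2, tile_origin, `+`)
    out[[i]] <- structure(
      list(cell_id = as.integer(id),
           centroid = unname(ctr),
           area_px = nrow(px),
           bbox = unname(bb),
           contour = contour,
           tile_origin = tile_origin),
      class = "cell_object")
  }
  out
}

#' Crop a fixed-size patch centred on a cell
#'
#' The centroid is rounded half-away-from-zero to a pixel index and a
#' `size x size` box `[r - size/2, r + size/2)` is cut; pixels falling
#' outside the slide are filled by edge replication, which preserves local
#' stain statistics at slide borders.
#'
#' @param slide RGB raster in slide coordinates.
#' @param centroid numeric `(row, col)`, 0-based.
#' @param size even patch side, default 64.
#' @return a `size x size x 3` raster.
#' @export
crop_cell <- function(slide, centroid, size = 64) {
  check_raster(slide)
  stopifnot(size %% 2 == 0, size > 0)
  rr <- trunc(centroid[1] + sign(centroid[1]) * 0.5)
  cc <- trunc(centroid[2] + sign(centroid[2]) * 0.5)
  h <- dim(slide)[1]; w <- dim(slide)[2]
  rows <- (rr - size / 2):(rr + size / 2 - 1)   # 0-based
  cols <- (cc - size / 2):(cc + size / 2 - 1)
  rows <- pmin(pmax(rows, 0), h - 1) + 1
  cols <- pmin(pmax(cols, 0), w - 1) + 1
  slide[rows, cols, , drop = FALSE]
}

#' Merge two per-pixel class layers, second layer taking priority
#'
#' Inference runs segmentation twice (a small fixed diameter for the tiny
#' cells of early regeneration, and automatic diameter for mature fibers) and
#' overlays the resulting class maps, with the automatic-diameter layer
#' (layer 1) taking precedence wherever it detected anything.  `0` is the
#' no-detection sentinel.
#'
#' @param layer0,layer1 integer class matrices of the same shape.
#' @return merged integer class matrix.
#' @export
merge_layers <- function(layer0, layer1) {
  if (!all(dim(layer0) == dim(layer1)))
    stop("layer shapes differ", call. = FALSE)
  ifelse(layer1 != 0, layer1, layer0)
}

#' Cell-area rate of a slide
#'
#' Fraction of the stained-tissue area covered by segmented cells: the count
#' of segmented pixels inside the tissue mask divided by the tissue pixel
#' count.
#'
#' @param mask integer label matrix over the slide (0 = background).
#' @param tissue a [detect_tissue()] result.
#' @return a number in `[0, 1]`.
#' @export
cell_area_rate <- function(mask, tissue) {
  stopifnot(inherits(tissue, "tissue_mask"))
  if (tissue$area_px == 0)
    stop("tissue mask is empty: cell-area rate undefined", call. = FALSE)
  sum(mask > 0 & tissue$mask) / tissue$area_px
}
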