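#' Feature-extractor configuration
#'
#' Cell crops are embedded into a D-dimensional feature space before
#' classification.  The intended production backend is a pretrained
#' self-supervised vision transformer (ViT-B/8-style student checkpoint with
#' average-pooled patch tokens); since its output dimensionality depends on
#' the checkpoint and pooling composition, `D` is configuration, with 1536
#' (class token + pooled patch tokens) the conventional default.  Such a
#' backend is wired in via `backend = "custom"` and a function
#' `f(patch) -> numeric(D)`.  The built-in `"handcrafted"` backend is a
#' deterministic 64-dimensional descriptor that needs no weights and
#' separates the phase-typical appearances (colour, haziness, size cues) the
#' synthetic phantoms produce.
#'
#' @param backend `"handcrafted"` or `"custom"`.
#' @param D output dimensionality (default 64 handcrafted, 1536 custom).
#' @param pooling_flag logical, recorded for external backends that pool
#'   patch tokens.
#' @param fun for `"custom"`: function mapping a `64 x 64 x 3` raster to a
#'   length-`D` numeric vector.
#' @return an object of class `extractor_config`.
#' @export
extractor_config <- function(backend = "handcrafted",
                             D = if (backend == "handcrafted") 64L else 1536L,
                             pooling_flag = TRUE, fun = NULL) {
  if (!backend %in% c("handcrafted", "custom"))
    stop("unknown feature backend: ", backend, call. = FALSE)
  if (D <= 0) stop("D must be positive", call. = FALSE)
  if (backend == "custom" && !is.function(fun))
    stop("custom backend requires `fun`", call. = FALSE)
  structure(list(backend = backend, D = as.integer(D),
                 pooling_flag = isTRUE(pooling_flag), fun = fun),
            class = "extractor_config")
}

#' Extract features for a list of cell crops
#'
#' @param patches list of `64 x 64 x 3` rasters.
#' @param config an [extractor_config()].
#' @return an `N x D` numeric matrix, row i the feature vector of patch i.
#'   Pure function: identical patches map to identical rows.
#' @export
extract_features <- function(patches, config = extractor_config()) {
  D <- config$D
  if (!length(patches)) return(matrix(numeric(0), nrow = 0, ncol = D))
  f <- if (config$backend == "handcrafted") handcrafted_descriptor else config$fun
  out <- matrix(NA_real_, nrow = length(patches), ncol = D)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (length(dim(p)) != 3 || dim(p)[1] != 64 || dim(p)[2] != 64)
      stop("patch ", i, " is not 64 x 64 x 3", call. = FALSE)
    v <- f(p)
    if (length(v) != D || any(!is.finite(v)))
      stop("backend returned a malformed feature vector for patch ", i,
           call. = FALSE)
    out[i, ] <- v
  }
  out
}

#' Handcrafted 64-dimensional cell-crop descriptor
#'
#' Deterministic stand-alone descriptor for a `64 x 64` RGB crop:
#' \itemize{
#'   \item per-channel 8-bin intensity histograms, L1-normalised (24 dims);
#'   \item per-channel mean and standard deviation, scaled by 1/255 (6);
#'   \item gradient-magnitude mean, standard deviation and 8-bin histogram
#'     entropy on the luminance image (3) -- all exactly 0 on a constant
#'     crop;
#'   \item mean luminance (scaled) over 8 concentric rings around the crop
#'     centre (8) -- invariant to 90-degree rotation by construction;
#'   \item grey-level co-occurrence contrast and homogeneity at offsets
#'     (0,1) and (1,0) on 8-level quantised luminance (4);
#'   \item central 12 x 12 window: per-channel mean and standard deviation
#'     (6) and an 8-bin luminance histogram (8) -- the crop is centred on a
#'     cell, so these describe the cell itself rather than its
#'     neighbourhood, which matters when the centred cell is small;
#'   \item zero padding to D = 64 (5 dims).
#' }
#' Colour histograms and channel means describe the neighbourhood context;
#' the central-window block carries the centred cell's own colour; gradient
#' and co-occurrence terms carry the haziness/texture cues.
#'
#' @param patch a `64 x 64 x 3` raster.
#' @return numeric vector of length 64, all entries finite.
#' @export
handcrafted_descriptor <- function(patch) {
  stopifnot(length(dim(patch)) == 3, dim(patch)[1] == 64, dim(patch)[2] == 64)
  v <- numeric(0)
  # 8-bin per-channel histograms (bin width 32 over [0, 256))
  for (ch in 1:3) {
    b <- pmin(7L, as.integer(patch[, , ch]) %/% 32L)
    h <- tabulate(b + 1L, nbins = 8)
    v <- c(v, h / sum(h))
  }
  # channel means / sds
  for (ch in 1:3) v <- c(v, mean(patch[, , ch]) / 255)
  for (ch in 1:3) v <- c(v, stats::sd(patch[, , ch]) / 255)
  # gradient statistics on luminance
  g <- raster_gray(patch) / 255
  gx <- g[, c(2:64, 64)] - g[, c(1, 1:63)]
  gy <- g[c(2:64, 64), ] - g[c(1, 1:63), ]
  gm <- sqrt(gx^2 + gy^2)
  gsd <- if (max(gm) > 0) stats::sd(gm) else 0
  gent <- 0
  if (max(gm) > 0) {
    hb <- tabulate(pmin(7L, as.integer(gm / max(gm) * 8)) + 1L, nbins = 8)
    ph <- hb / sum(hb)
    ph <- ph[ph > 0]
    gent <- -sum(ph * log(ph))
  }
  v <- c(v, mean(gm), gsd, gent)
  # radial profile: 8 rings by distance from the crop centre
  ctr <- (64 + 1) / 2
  dist <- sqrt(outer((seq_len(64) - ctr)^2, (seq_len(64) - ctr)^2, `+`))
  ring <- pmin(7L, as.integer(dist / (max(dist) + 1e-9) * 8))
  for (r in 0:7) {
    sel <- ring == r
    v <- c(v, if (any(sel)) mean(g[sel]) else 0)
  }
  # co-occurrence contrast / homogeneity at offsets (0,1) and (1,0)
  q <- matrix(pmin(7L, as.integer(patch[, , 1] + patch[, , 2] + patch[, , 3]) %/% 96L),
              64, 64)
  for (off in list(c(0L, 1L), c(1L, 0L))) {
    a <- q[seq_len(64 - off[1]), seq_len(64 - off[2])]
    b <- q[seq_len(64 - off[1]) + off[1], seq_len(64 - off[2]) + off[2]]
    d2 <- (a - b)^2
    v <- c(v, mean(d2), mean(1 / (1 + d2)))
  }
  # central 12 x 12 window (rows/cols 27..38): the centred cell itself
  win <- 27:38
  for (ch in 1:3) v <- c(v, mean(patch[win, win, ch]) / 255)
  for (ch in 1:3) v <- c(v, stats::sd(patch[win, win, ch]) / 255)
  gc_ <- g[win, win]
  hc <- tabulate(pmin(7L, as.integer(gc_ * 255) %/% 32L) + 1L, nbins = 8)
  v <- c(v, hc / sum(hc))
  c(v, numeric(64 - length(v)))
}
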