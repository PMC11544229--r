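#' Cardiotoxin-like recovery schedule
#'
#' Day-indexed class-proportion schedule emulating regeneration after a
#' myotoxin injection: day 0 entirely stable tissue; day 3 dominated by
#' ghost fibers and infiltrate (early); proliferating myoblasts (mid)
#' peaking around day 5; fusing and maturing myotubes (late) dominant from
#' day 7 and still prevalent at day 14, because regenerated fibers keep
#' their central myonuclei -- the defining late-phase feature -- for weeks
#' after the insult.  These defaults define the study conditions for every
#' simulation in the package.
#'
#' @return a [day_proportion_table()] for days 0, 3, 5, 7, 14.
#' @export
ctx_schedule <- function() {
  day_proportion_table(
    c(0, 3, 5, 7, 14),
    rbind(c(1.00, 0.00, 0.00, 0.00),
          c(0.05, 0.70, 0.20, 0.05),
          c(0.05, 0.30, 0.40, 0.25),
          c(0.10, 0.10, 0.25, 0.55),
          c(0.20, 0.00, 0.05, 0.75)))
}

#' Default per-class phantom appearance parameters
#'
#' Radii in pixels and RGB fill colours for the four phases: stable = large
#' fibers, pink with a darker boundary; early = pale, hazy ghost-fiber
#' outlines; mid = small, round, dark myoblasts; late = medium myotubes
#' with a central nucleus dot.  Chosen so the handcrafted descriptor
#' separates the classes -- a test-design constraint, not a biological
#' claim.
#' @keywords internal
phantom_cell_specs <- function() {
  list(
    stable = list(radius = c(12, 20), fill = c(235, 150, 170),
                  border = c(120, 60, 90), haze = 0.08, dot = FALSE),
    early  = list(radius = c(9, 16),  fill = c(215, 200, 225),
                  border = NULL,       haze = 0.55, dot = FALSE),
    mid    = list(radius = c(4, 7),   fill = c(130, 85, 160),
                  border = NULL,       haze = 0.08, dot = FALSE),
    late   = list(radius = c(8, 13),  fill = c(225, 170, 120),
                  border = NULL,       haze = 0.08, dot = TRUE))
}

#' Phantom configuration
#'
#' @param size `c(h, w)` canvas size in pixels.
#' @param day day label attached to the phantom.
#' @param proportions length-4 target per-class pixel proportions (simplex).
#' @param coverage target fraction of the canvas covered by cells
#'   (default 0.35, a typical tissue fill).
#' @param cell_specs per-class appearance list (see
#'   `myophase:::phantom_cell_specs`).
#' @param noise_sd Gaussian channel noise added to the rendered image
#'   (default 2, mild scanner noise).
#' @param tolerance acceptable per-class deviation of realized from target
#'   proportions (default 0.05).
#' @param max_attempts dart-throwing placement budget.
#' @param seed RNG seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(size = c(512, 512), day = 0,
                           proportions = c(1, 0, 0, 0), coverage = 0.35,
                           cell_specs = phantom_cell_specs(), noise_sd = 2,
                           tolerance = 0.05, max_attempts = 20000L,
                           seed = 1L) {
  stopifnot(length(size) == 2, all(size > 0),
            abs(sum(proportions) - 1) < 1e-9, all(proportions >= 0),
            coverage > 0, coverage < 1)
  structure(list(size = as.integer(size), day = day,
                 proportions = proportions, coverage = coverage,
                 cell_specs = cell_specs, noise_sd = noise_sd,
                 tolerance = tolerance, max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic tissue phantom
#'
#' Places non-overlapping elliptical cells on a white canvas by seeded
#' dart-throwing, class by class, until each class's pixel count reaches its
#' target (canvas area x coverage x proportion) within tolerance or the
#' placement budget runs out (then a warning reports the realized
#' proportions).  Returns the rendered image, the ground-truth label mask,
#' the per-cell class table, a rough colour annotation (class palette over
#' the cell regions, white elsewhere), and the realized per-class pixel
#' proportions.
#'
#' @param config a [phantom_config()].
#' @param scheme a [class_scheme()] supplying the annotation palette.
#' @return an object of class `phantom_sample`: `list(image, gt_mask,
#'   gt_class, rough_annotation, realized_proportions, day, config)`.
#' @export
generate_tissue_phantom <- function(config = phantom_config(),
                                    scheme = class_scheme()) {
  h <- config$size[1]; w <- config$size[2]
  specs <- config$cell_specs
  K <- length(specs)
  target <- config$proportions * config$coverage * h * w
  labels <- matrix(0L, h, w)
  image <- new_raster(h, w)
  annot <- new_raster(h, w)
  gt_class <- integer(0)
  counts <- numeric(K)
  next_id <- 1L
  withr::with_seed(config$seed, {
    attempts <- 0L
    while (attempts < config$max_attempts) {
      deficit <- target - counts
      if (all(deficit <= config$tolerance * config$coverage * h * w)) break
      k <- which.max(deficit)
      attempts <- attempts + 1L
      sp <- specs[[k]]
      a <- stats::runif(1, sp$radius[1], sp$radius[2])
      b <- stats::runif(1, sp$radius[1], sp$radius[2])
      th <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      px <- ellipse_pixels(cy, cx, a, b, th, h, w, margin = 2)
      if (is.null(px)) next
      if (any(labels[px$outer] != 0)) next
      # render the cell
      rendered <- render_cell(image, px, sp)
      image <- rendered
      labels[px$inner] <- next_id
      for (ch in 1:3) {
        plane <- annot[, , ch]
        plane[px$inner] <- scheme$colors[k, ch]
        annot[, , ch] <- plane
      }
      counts[k] <- counts[k] + length(px$inner)
      gt_class <- c(gt_class, k)
      next_id <- next_id + 1L
    }
    if (attempts >= config$max_attempts)
      warning("phantom placement budget exhausted; realized proportions: ",
              paste(round(counts / max(sum(counts), 1), 3), collapse = ", "),
              call. = FALSE)
    if (config$noise_sd > 0) {
      image <- image + array(stats::rnorm(h * w * 3, 0, config$noise_sd),
                             dim = dim(image))
      image <- pmin(pmax(round(image), 0), 255)
    }
  })
  realized <- if (sum(counts) > 0) counts / sum(counts) else counts
  structure(list(image = image, gt_mask = labels, gt_class = gt_class,
                 rough_annotation = annot, realized_proportions = realized,
                 day = config$day, config = config),
            class = "phantom_sample")
}

#' Pixel membership of an ellipse (inner) and of its clearance margin
#' @keywords internal
ellipse_pixels <- function(cy, cx, a, b, th, h, w, margin = 2) {
  rmax <- max(a, b) + margin
  y0 <- floor(cy - rmax); y1 <- ceiling(cy + rmax)
  x0 <- floor(cx - rmax); x1 <- ceiling(cx + rmax)
  if (y0 < 1 || x0 < 1 || y1 > h || x1 > w) return(NULL)
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <-  dy * cos(th) + dx * sin(th)
  v <- -dy * sin(th) + dx * cos(th)
  r2 <- (u / a)^2 + (v / b)^2
  r2m <- (u / (a + margin))^2 + (v / (b + margin))^2
  grid <- cbind(rep(ys, times = length(xs)), rep(xs, each = length(ys)))
  lin <- function(sel) (grid[sel, 2] - 1) * h + grid[sel, 1]
  inner <- lin(as.vector(r2) <= 1)
  if (!length(inner)) return(NULL)
  list(inner = inner, outer = lin(as.vector(r2m) <= 1),
       r2 = as.vector(r2)[as.vector(r2) <= 1])
}

#' Paint one cell onto the image
#' @keywords internal
render_cell <- function(image, px, sp) {
  u <- sqrt(px$r2)                       # normalized radius in [0, 1]
  wgt <- pmin(1, pmax(0, (1 - u) / max(sp$haze, 1e-9)))  # haze falloff
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[px$inner] <- 255 + wgt * (sp$fill[ch] - 255)
    if (!is.null(sp$border)) {
      edge <- px$inner[u > 0.82]
      plane[edge] <- sp$border[ch]
    }
    if (isTRUE(sp$dot)) {
      core <- px$inner[u < 0.25]
      plane[core] <- c(90, 60, 110)[ch]
    }
    image[, , ch] <- plane
  }
  image
}

#' Feature-simulation configuration
#'
#' Class-conditional isotropic Gaussian features with day-indexed mixing
#' proportions -- the statistical structure LLP training assumes.  Class
#' means default to scaled coordinate axes, `mu_k = s e_k / sqrt(2)` with
#' `s = separation x sigma`, so every pair of class means is exactly
#' `separation x sigma` apart.
#'
#' @param D feature dimensionality (requires `D >= K` for default means).
#' @param K number of classes.
#' @param separation pairwise mean separation in units of `sigma`.
#' @param sigma shared isotropic standard deviation.
#' @param means optional explicit `K x D` mean matrix (overrides
#'   `separation`).
#' @param day_props a [day_proportion_table()] of mixing proportions
#'   (default [ctx_schedule()]).
#' @param n_per_day instances per day.
#' @param seed RNG seed.
#' @return an object of class `feature_sim_config`.
#' @export
feature_sim_config <- function(D = 32L, K = 4L, separation = 6, sigma = 1,
                               means = NULL, day_props = ctx_schedule(),
                               n_per_day = 800L, seed = 1L) {
  stopifnot(D >= 1, K >= 2, sigma > 0)
  if (is.null(means)) {
    stopifnot(D >= K)
    means <- matrix(0, K, D)
    for (k in seq_len(K)) means[k, k] <- separation * sigma / sqrt(2)
  }
  stopifnot(nrow(means) == K, ncol(means) == D)
  structure(list(D = as.integer(D), K = as.integer(K), means = means,
                 sigma = sigma, day_props = day_props,
                 n_per_day = as.integer(n_per_day), seed = as.integer(seed)),
            class = "feature_sim_config")
}

#' Generate a class-conditional Gaussian feature dataset
#'
#' For each day, instance classes are drawn from the day's mixing
#' proportions and features from the class Gaussian.  Fully seeded.
#'
#' @param config a [feature_sim_config()].
#' @return `list(features, day, class)`: an `N x D` matrix, day labels
#'   (character) and true 1-based class indices.
#' @export
generate_feature_dataset <- function(config = feature_sim_config()) {
  P <- as_day_matrix(config$day_props)
  days <- rownames(P)
  n <- config$n_per_day
  N <- n * length(days)
  X <- matrix(NA_real_, N, config$D)
  day_out <- character(N); cls <- integer(N)
  withr::with_seed(config$seed, {
    at <- 0L
    for (d in days) {
      ks <- sample.int(config$K, n, replace = TRUE, prob = P[d, ])
      noise <- matrix(stats::rnorm(n * config$D, 0, config$sigma),
                      n, config$D)
      X[at + seq_len(n), ] <- config$means[ks, , drop = FALSE] + noise
      day_out[at + seq_len(n)] <- d
      cls[at + seq_len(n)] <- ks
      at <- at + n
    }
  })
  list(features = X, day = day_out, class = cls)
}

#' Sixteen-fold geometric and photometric augmentation
#'
#' The augmentation scheme used for slide tiles: the 8 geometric variants
#' (rotations by 0/90/180/270 degrees, each with and without a vertical
#' flip) are enumerated deterministically, and each variant additionally
#' yields one seeded photometric-jitter copy (brightness shift, contrast
#' scale and gamma each applied independently with probability 0.5), for
#' exactly 16 outputs per input.  When paired masks are supplied they follow
#' the geometric transforms only (a jitter copy shares its variant's mask),
#' so image/mask correspondence is preserved.
#'
#' @param images list of square RGB rasters.
#' @param seed RNG seed for the jitter draws.
#' @param masks optional list of matrices paired with `images`.
#' @param jitter_p probability of each photometric operation (default 0.5;
#'   set to 0 for bit-identical jitter copies).
#' @return if `masks` is `NULL`, a list of `16 * length(images)` rasters
#'   (for each input: its 8 geometric variants, then their 8 jitter
#'   copies); otherwise `list(images, masks)` with aligned entries.
#' @export
augment_geometric_photometric <- function(images, seed = 1L, masks = NULL,
                                          jitter_p = 0.5) {
  for (im in images)
    if (dim(im)[1] != dim(im)[2])
      stop("augmentation requires square rasters", call. = FALSE)
  out_imgs <- list(); out_masks <- list()
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(images)) {
      geo <- list(); geo_m <- list()
      for (flip in c(FALSE, TRUE)) {
        im <- images[[i]]; mk <- if (!is.null(masks)) masks[[i]]
        if (flip) {
          im <- flip_raster(im)
          if (!is.null(mk)) mk <- mk[nrow(mk):1, , drop = FALSE]
        }
        for (rot in 0:3) {
          geo[[length(geo) + 1]] <- im
          if (!is.null(masks)) geo_m[[length(geo_m) + 1]] <- mk
          im <- rot90_raster(im)
          if (!is.null(mk)) mk <- rot90_matrix(mk)
        }
      }
      jit <- lapply(geo, photometric_jitter, p = jitter_p)
      out_imgs <- c(out_imgs, geo, jit)
      if (!is.null(masks)) out_masks <- c(out_masks, geo_m, geo_m)
    }
  })
  if (is.null(masks)) out_imgs else list(images = out_imgs, masks = out_masks)
}

#' Rotate a square raster 90 degrees clockwise
#' @keywords internal
rot90_raster <- function(x) {
  out <- x
  for (ch in 1:3) out[, , ch] <- rot90_matrix(x[, , ch])
  out
}

#' @keywords internal
rot90_matrix <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Flip a raster vertically (reverse rows)
#' @keywords internal
flip_raster <- function(x) x[dim(x)[1]:1, , , drop = FALSE]

#' Seeded photometric jitter (brightness/contrast/gamma, each with prob p)
#' @keywords internal
photometric_jitter <- function(x, p = 0.5) {
  if (stats::runif(1) < p) x <- x + stats::runif(1, -30, 30)
  if (stats::runif(1) < p) {
    f <- stats::runif(1, 0.8, 1.2)
    x <- (x - mean(x)) * f + mean(x)
  }
  if (stats::runif(1) < p) {
    g <- stats::runif(1, 0.8, 1.25)
    x <- 255 * (pmin(pmax(x, 0), 255) / 255)^g
  }
  pmin(pmax(round(x), 0), 255)
}

#' Random fixed-size crops from a tile
#'
#' `n` crops with uniformly random top-left corners fully inside the tile;
#' seeded.  Used to build LLP training instances from tiles.
#'
#' @param tile RGB raster.
#' @param n number of crops (default 100).
#' @param size crop side (default 64).
#' @param seed RNG seed.
#' @return list of `size x size x 3` rasters with a `positions` attribute
#'   (`n x 2` matrix of 0-based top-left corners).
#' @export
random_crops <- function(tile, n = 100L, size = 64L, seed = 1L) {
  check_raster(tile)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  if (size > h || size > w)
    stop("crop size exceeds tile side", call. = FALSE)
  if (n == 0) return(structure(list(),
                               positions = matrix(numeric(0), 0, 2)))
  pos <- withr::with_seed(as.integer(seed),
    cbind(sample.int(h - size + 1, n, replace = TRUE) - 1L,
          sample.int(w - size + 1, n, replace = TRUE) - 1L))
  crops <- lapply(seq_len(n), function(i)
    tile[pos[i, 1] + seq_len(size), pos[i, 2] + seq_len(size), , drop = FALSE])
  structure(crops, positions = pos)
}
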