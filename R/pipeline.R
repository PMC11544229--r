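#' Pipeline configuration
#'
#' Gathers every knob of the slide-level pipeline: tiling and crop sizes,
#' the two segmentation layer configs (a small fixed diameter to catch the
#' tiny cells of early regeneration, and automatic diameter for mature
#' fibers; the second layer wins where both detect), the feature extractor,
#' the training config, the sigmoid recovery model and one master seed.
#'
#' @param scheme a [class_scheme()].
#' @param tile_size tile side (default 256).
#' @param crop_size cell-crop side (default 64).
#' @param layer0,layer1 [segmenter_config()]s for the two passes.
#' @param extractor an [extractor_config()].
#' @param train a [train_config()].
#' @param sigmoid a [sigmoid_model()].
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scheme = class_scheme(), tile_size = 256L,
                            crop_size = 64L,
                            layer0 = segmenter_config(diameter = 5),
                            layer1 = segmenter_config(diameter = NULL),
                            extractor = extractor_config(),
                            train = train_config(),
                            sigmoid = sigmoid_model(), seed = 1L) {
  structure(list(scheme = scheme, tile_size = as.integer(tile_size),
                 crop_size = as.integer(crop_size), layer0 = layer0,
                 layer1 = layer1, extractor = extractor, train = train,
                 sigmoid = sigmoid, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Segment a whole slide with the two-layer strategy
#'
#' Tiles the slide, runs both segmentation passes per tile, and reassembles
#' slide-sized label masks.  Labels are re-numbered to be unique across
#' tiles.
#'
#' @param wsi RGB raster.
#' @param config a [pipeline_config()].
#' @return `list(mask0, mask1, grid)`: slide-sized label masks for layer 0
#'   and layer 1 plus the tile grid.
#' @export
segment_slide <- function(wsi, config = pipeline_config()) {
  grid <- split_to_grid(wsi, config$tile_size)
  seg_one <- function(layer_cfg) {
    offset <- 0L
    outs <- lapply(grid$tiles, function(t0) {
      lab <- run_backend(t0$raster, layer_cfg)
      lab[lab > 0] <- lab[lab > 0] + offset
      offset <<- offset + max(0L, max(lab))
      lab
    })
    reassemble(grid, outs)
  }
  list(mask0 = seg_one(config$layer0), mask1 = seg_one(config$layer1),
       grid = grid)
}

#' Classify every cell of a slide and build its class map
#'
#' For each segmentation layer: extract cells, crop each cell, embed the
#' crops, classify, and paint the cell's pixels with its class code; then
#' overlay the two layers with layer 1 priority.  Returns the merged class
#' map, the per-cell table and the slide's class proportions.
#'
#' @param wsi RGB raster.
#' @param model a trained `llp_classifier`.
#' @param config a [pipeline_config()].
#' @return `list(class_map, cells, proportions, cell_area_rate, tissue)`;
#'   `cells` is a data frame (cell_id, layer, row, col, area_px, class and
#'   the K confidences).  `proportions` is `NA` when no cell was detected.
#' @export
run_slide <- function(wsi, model, config = pipeline_config()) {
  seg <- segment_slide(wsi, config)
  K <- config$scheme$K
  layer_maps <- list()
  cell_rows <- list()
  for (li in 0:1) {
    mask <- if (li == 0) seg$mask0 else seg$mask1
    cmap <- matrix(0L, nrow(mask), ncol(mask))
    cells <- extract_cells(mask)
    if (length(cells)) {
      crops <- lapply(cells, function(cl)
        crop_cell(wsi, cl$centroid, config$crop_size))
      feats <- extract_features(crops, config$extractor)
      conf <- forward(model$params, feats)
      cls <- max.col(conf, ties.method = "first")
      for (i in seq_along(cells))
        cmap[mask == cells[[i]]$cell_id] <- cls[i]
      df <- data.frame(
        cell_id = vapply(cells, `[[`, integer(1), "cell_id"),
        layer = li,
        row = vapply(cells, function(cl) cl$centroid[1], numeric(1)),
        col = vapply(cells, function(cl) cl$centroid[2], numeric(1)),
        area_px = vapply(cells, `[[`, integer(1), "area_px"),
        class = cls)
      for (k in seq_len(K)) df[[paste0("conf", k)]] <- conf[, k]
      cell_rows[[li + 1]] <- df
    }
    layer_maps[[li + 1]] <- cmap
  }
  class_map <- merge_layers(layer_maps[[1]], layer_maps[[2]])
  tissue <- detect_tissue(wsi)
  seg_union <- (seg$mask0 > 0) | (seg$mask1 > 0)
  car <- if (tissue$area_px > 0) sum(seg_union & tissue$mask) / tissue$area_px
         else NA_real_
  props <- if (any(class_map != 0))
    classmap_proportions(class_map, K = K) else rep(NA_real_, K)
  list(class_map = class_map,
       cells = if (length(cell_rows)) do.call(rbind, cell_rows) else NULL,
       proportions = props, cell_area_rate = car, tissue = tissue)
}

#' Render a class map as an RGB raster
#'
#' @param class_map integer class matrix (0 = no detection, painted white).
#' @param scheme a [class_scheme()].
#' @return RGB raster.
#' @export
colorize_class_map <- function(class_map, scheme = class_scheme()) {
  h <- nrow(class_map); w <- ncol(class_map)
  out <- new_raster(h, w, fill = scheme$sentinel_color)
  for (k in seq_len(scheme$K)) {
    sel <- class_map == k
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- scheme$colors[k, ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Build LLP training instances from slides
#'
#' Samples crop centres uniformly among each slide's annotated pixels
#' (seeded), so a crop lands on a region of class k with probability equal
#' to k's annotated pixel proportion -- the alignment that lets day-level
#' pixel proportions supervise crop-level instances.  When no annotation is
#' supplied the saturation tissue mask is used instead.  Crops are embedded
#' with the configured extractor.
#'
#' @param slides list of RGB rasters.
#' @param days day label of each slide.
#' @param n_crops_per_slide crops sampled per slide.
#' @param config a [pipeline_config()].
#' @param annotations optional list of rough-annotation rasters paired with
#'   `slides`; crop centres are drawn from their non-white pixels.
#' @return `list(features, day)` ready for [train_classifier()].
#' @export
sample_training_instances <- function(slides, days, n_crops_per_slide = 400L,
                                      config = pipeline_config(),
                                      annotations = NULL) {
  stopifnot(length(slides) == length(days))
  feats <- list(); day_out <- character(0)
  for (i in seq_along(slides)) {
    wsi <- slides[[i]]
    if (!is.null(annotations)) {
      ar <- annotations[[i]]
      m <- !(ar[, , 1] == 255 & ar[, , 2] == 255 & ar[, , 3] == 255)
    } else {
      m <- detect_tissue(wsi)$mask
    }
    px <- which(m, arr.ind = TRUE)
    if (!nrow(px)) next
    sel <- withr::with_seed(config$seed + i,
      px[sample.int(nrow(px), n_crops_per_slide, replace = TRUE), ,
         drop = FALSE])
    crops <- lapply(seq_len(nrow(sel)), function(j)
      crop_cell(wsi, c(sel[j, 1] - 1, sel[j, 2] - 1), config$crop_size))
    feats[[length(feats) + 1]] <- extract_features(crops, config$extractor)
    day_out <- c(day_out, rep(as.character(days[i]), nrow(sel)))
  }
  list(features = do.call(rbind, feats), day = day_out)
}

#' Train the pipeline classifier from slides and rough annotations
#'
#' Computes the day-level proportions from the rough annotations, samples
#' tissue-restricted training crops and trains the classifier in the
#' configured mode.
#'
#' @param slides list of RGB rasters.
#' @param annotations list of `list(raster, day)` rough annotations.
#' @param days day label per slide.
#' @param n_crops_per_slide crops sampled per slide.
#' @param config a [pipeline_config()].
#' @return `list(model, day_props)`.
#' @export
train_pipeline <- function(slides, annotations, days,
                           n_crops_per_slide = 400L,
                           config = pipeline_config()) {
  day_props <- proportions_from_annotations(annotations, config$scheme)
  inst <- sample_training_instances(
    slides, days, n_crops_per_slide, config,
    annotations = lapply(annotations, `[[`, "raster"))
  model <- train_classifier(inst$features, inst$day, day_props, config$train)
  list(model = model, day_props = day_props)
}

#' Write per-slide pipeline outputs to disk
#'
#' Emits the coloured class map (PNG), the per-cell table, the slide
#' proportions and the recovery summary as headed CSVs -- the interchange
#' formats tying the pipeline stages together.
#'
#' @param result a [run_slide()] result.
#' @param slide_id identifier used in file names.
#' @param out_dir output directory (created if needed).
#' @param weights optional [fit_weights()] result; when present a
#'   `summary.csv` row is written too.
#' @param scheme a [class_scheme()].
#' @return named character vector of the files written, invisibly.
#' @export
write_slide_outputs <- function(result, slide_id, out_dir,
                                weights = NULL, scheme = class_scheme()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, paste0(slide_id, "_", name))
  files <- c(class_map = f("class_map.png"))
  write_raster(colorize_class_map(result$class_map, scheme), files[["class_map"]])
  files["cells"] <- f("cells.csv")
  utils::write.csv(result$cells, files[["cells"]], row.names = FALSE)
  files["proportions"] <- f("proportions.csv")
  pr <- data.frame(slide = slide_id, t(result$proportions))
  names(pr)[-1] <- scheme$names
  utils::write.csv(pr, files[["proportions"]], row.names = FALSE)
  if (!is.null(weights) && !anyNA(result$proportions)) {
    files["summary"] <- f("summary.csv")
    utils::write.csv(
      recovery_summary(slide_id, result$proportions, weights,
                       result$cell_area_rate),
      files[["summary"]], row.names = FALSE)
  }
  invisible(files)
}

#' Generate and write a multi-day phantom bundle
#'
#' One directory per day (image, 16-bit ground-truth mask, per-cell class
#' table, rough annotation, JSON metadata with the realized proportions),
#' plus a manifest listing every file with its MD5 checksum.
#'
#' @param out_dir output directory.
#' @param schedule a [day_proportion_table()] (default [ctx_schedule()]).
#' @param n_slides slides per day.
#' @param size canvas size.
#' @param seed master seed.
#' @param scheme a [class_scheme()].
#' @return path of the manifest CSV, invisibly.
#' @export
cmd_synth <- function(out_dir, schedule = ctx_schedule(), n_slides = 1L,
                      size = c(512, 512), seed = 1L,
                      scheme = class_scheme()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  P <- as_day_matrix(schedule)
  manifest <- list()
  for (d in rownames(P)) {
    for (s in seq_len(n_slides)) {
      dd <- file.path(out_dir, paste0("day", d))
      dir.create(dd, showWarnings = FALSE)
      cfg <- phantom_config(size = size, day = as.numeric(d),
                            proportions = P[d, ],
                            seed = seed * 10000L + as.integer(as.numeric(d)) *
                              100L + s)
      ph <- generate_tissue_phantom(cfg, scheme)
      pre <- file.path(dd, paste0("slide", s))
      write_raster(ph$image, paste0(pre, "_image.png"))
      write_label_mask(ph$gt_mask, paste0(pre, "_gt_mask.tif"))
      write_raster(ph$rough_annotation, paste0(pre, "_rough_annotation.png"))
      utils::write.csv(data.frame(cell_id = seq_along(ph$gt_class),
                                  class = ph$gt_class),
                       paste0(pre, "_classes.csv"), row.names = FALSE)
      jsonlite::write_json(list(day = ph$day, seed = cfg$seed,
                                realized_proportions = ph$realized_proportions),
                           paste0(pre, "_meta.json"), digits = NA,
                           auto_unbox = TRUE)
      for (ext in c("_image.png", "_gt_mask.tif", "_rough_annotation.png",
                    "_classes.csv", "_meta.json"))
        manifest[[length(manifest) + 1]] <-
          data.frame(file = paste0(pre, ext),
                     md5 = unname(tools::md5sum(paste0(pre, ext))))
    }
  }
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(if (length(manifest)) do.call(rbind, manifest)
                   else data.frame(file = character(0), md5 = character(0)),
                   mf, row.names = FALSE)
  invisible(mf)
}

#' Write evaluation metrics as JSON
#'
#' @param metrics named list of metric objects (confusions, PRF tables, KL
#'   lists, ...).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}
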