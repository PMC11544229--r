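#' Day-level class-proportion table
#'
#' One proportion vector per day, the weak supervision signal of LLP
#' training.  Stored as a matrix with one row per day (rownames the day
#' labels as character) and one column per class; per-class pixel totals are
#' kept in the `"pixel_counts"` attribute when derived from annotations.
#'
#' @param days vector of day labels.
#' @param P numeric matrix, rows on the simplex, one per day.
#' @return a `day_proportion_table` (matrix with day rownames).
#' @export
day_proportion_table <- function(days, P) {
  P <- as.matrix(P)
  stopifnot(length(days) == nrow(P), !anyDuplicated(days))
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("each day's proportions must be nonnegative and sum to 1",
         call. = FALSE)
  rownames(P) <- as.character(days)
  structure(P, class = c("day_proportion_table", "matrix", "array"))
}

#' Coerce to a plain day x class matrix
#' @keywords internal
as_day_matrix <- function(x) {
  m <- unclass(as.matrix(x))
  if (is.null(rownames(m)))
    stop("day proportion table needs day rownames", call. = FALSE)
  m
}

#' Day-level class proportions from rough colour annotations
#'
#' Rough annotations are colour rasters in which broad pen strokes mark each
#' region's phase with the class colour and everything else (background,
#' undecidable regions) is white.  Pixels are counted per class colour with
#' exact palette matching by default (the annotations are flat-colour
#' paint strokes); `snap_tolerance` optionally snaps near-palette colours
#' (max channel distance) for annotations that survived lossy encoding.
#' Counts are pooled over all of a day's rasters before normalising, so
#' splitting one annotation into several files changes nothing.
#'
#' @param annotations list of `list(raster, day)` entries.
#' @param scheme a [class_scheme()].
#' @param snap_tolerance per-channel tolerance for palette matching
#'   (default 0 = exact).
#' @return a [day_proportion_table()] with per-class `pixel_counts`
#'   attribute (day x class matrix).
#' @export
proportions_from_annotations <- function(annotations, scheme = class_scheme(),
                                         snap_tolerance = 0) {
  K <- scheme$K
  days <- unique(vapply(annotations, function(a) as.character(a$day),
                        character(1)))
  counts <- matrix(0, nrow = length(days), ncol = K,
                   dimnames = list(days, scheme$names))
  for (a in annotations) {
    r <- a$raster
    check_raster(r)
    for (k in seq_len(K)) {
      col <- scheme$colors[k, ]
      hit <- abs(r[, , 1] - col[1]) <= snap_tolerance &
             abs(r[, , 2] - col[2]) <= snap_tolerance &
             abs(r[, , 3] - col[3]) <= snap_tolerance
      counts[as.character(a$day), k] <- counts[as.character(a$day), k] + sum(hit)
    }
  }
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("day(s) with zero annotated pixels: ",
         paste(days[tot == 0], collapse = ", "), call. = FALSE)
  tab <- day_proportion_table(days, counts / tot)
  attr(tab, "pixel_counts") <- counts
  tab
}

#' Class proportions of a per-pixel class map within the cell area
#'
#' `p_hat_k` = pixels of class `k` inside the cell mask divided by the total
#' cell-mask pixel count; pixels outside the mask are never counted.
#'
#' @param class_raster integer class matrix (0 = no detection).
#' @param cell_mask logical matrix of the same shape selecting cell pixels;
#'   default: every detected pixel.
#' @param K number of classes.
#' @return length-`K` proportion vector.
#' @export
classmap_proportions <- function(class_raster, cell_mask = class_raster != 0,
                                 K = 4L) {
  stopifnot(all(dim(class_raster) == dim(cell_mask)))
  vals <- class_raster[cell_mask]
  if (!length(vals))
    stop("empty cell mask: proportions undefined", call. = FALSE)
  tabulate(vals, nbins = K) / length(vals)
}

#' Sigmoid recovery model
#'
#' Recovery over days is anchored to the logistic curve
#' `sigma(x) = 1 / (1 + exp(-a (x - d)))`: the gain `a > 0` is the recovery
#' speed and the inflection day `d` is when the tissue switches to recovery.
#' The reference calibration for cardiotoxin injury is `a = 0.65`,
#' `d = 6` days.
#'
#' @param a gain, `> 0`.
#' @param d inflection day.
#' @return an object of class `sigmoid_model`.
#' @export
sigmoid_model <- function(a = 0.65, d = 6) {
  stopifnot(a > 0)
  structure(list(a = a, d = d), class = "sigmoid_model")
}

#' @rdname sigmoid_model
#' @param x day (or any abscissa); vectorised.
#' @param model a `sigmoid_model`.
#' @return `sigmoid`: values in `(0, 1)`, strictly increasing in `x`.
#' @export
sigmoid <- function(x, model = sigmoid_model()) {
  1 / (1 + exp(-model$a * (x - model$d)))
}

#' Fit recovery weights by least squares against the sigmoid model
#'
#' Solves `min_omega || P omega - sigma(days) ||^2` by ordinary least
#' squares (SVD pseudo-inverse, so a rank-deficient design yields the
#' minimum-norm solution with a warning), then clips `omega` to `[0, 1]` --
#' the declared domain of the weights -- and reports the pre-clip residual
#' norm so active clipping is detectable.
#'
#' @param P `M x K` matrix of per-slide (or per-day pooled) true
#'   proportions, rows on the simplex.
#' @param days length-`M` numeric day of each row.
#' @param model a [sigmoid_model()].
#' @return an object of class `recovery_weights`: `list(omega, omega_raw,
#'   fit_residual)`.
#' @export
fit_weights <- function(P, days, model = sigmoid_model()) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(days))
  t_ <- sigmoid(as.numeric(days), model)
  sv <- svd(P)
  tol <- max(dim(P)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (sum(pos) < ncol(P))
    warning("rank-deficient proportion design: returning the minimum-norm ",
            "least-squares solution", call. = FALSE)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  omega_raw <- as.numeric(sv$v %*% (dinv * (t(sv$u) %*% t_)))
  structure(list(omega = pmin(pmax(omega_raw, 0), 1),
                 omega_raw = omega_raw,
                 fit_residual = sqrt(sum((P %*% omega_raw - t_)^2))),
            class = "recovery_weights")
}

#' Recovery score of a slide
#'
#' Weighted sum of the slide's class proportions,
#' `score = sum_k p_hat_k omega_k`; lies in `[0, 1]` because the weights are
#' clipped and the proportions are on the simplex.
#'
#' @param p_hat length-`K` proportion vector.
#' @param weights a [fit_weights()] result (or bare numeric weights).
#' @return scalar score.
#' @export
recovery_score <- function(p_hat, weights) {
  w <- if (inherits(weights, "recovery_weights")) weights$omega else weights
  stopifnot(length(p_hat) == length(w))
  sum(p_hat * w)
}

#' Summarise one slide
#'
#' @param slide_id identifier.
#' @param color_proportions class proportions of the slide's class map.
#' @param weights recovery weights.
#' @param cell_area_rate the slide's cell-area rate.
#' @return a one-row data frame: id, recovery score, cell-area rate and the
#'   per-class proportions.
#' @export
recovery_summary <- function(slide_id, color_proportions, weights,
                             cell_area_rate) {
  p <- as.numeric(color_proportions)
  df <- data.frame(slide = slide_id,
                   recovery_score = recovery_score(p, weights),
                   cell_area_rate = cell_area_rate)
  for (k in seq_along(p)) df[[paste0("p", k)]] <- p[k]
  df
}
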