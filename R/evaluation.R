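#' Intersection over union of two pixel sets
#'
#' @param a,b pixel sets: logical matrices (same shape) or vectors of linear
#'   pixel indices.
#' @return `|a intersect b| / |a union b|`; both-empty input is an error.
#' @export
iou <- function(a, b) {
  if (is.matrix(a)) a <- which(a)
  if (is.matrix(b)) b <- which(b)
  u <- length(union(a, b))
  if (u == 0) stop("IoU of two empty sets is undefined", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Per-object overlap table of two label masks
#'
#' Contingency of (gt label, pred label) pixel counts, plus each side's
#' areas; the workhorse behind [mean_iou()] and [f1_at_threshold()].
#' @keywords internal
overlap_table <- function(gt, pred) {
  stopifnot(all(dim(gt) == dim(pred)))
  gids <- sort(unique(gt[gt > 0]))
  pids <- sort(unique(pred[pred > 0]))
  inter <- matrix(0, length(gids), length(pids),
                  dimnames = list(gids, pids))
  both <- gt > 0 & pred > 0
  if (any(both)) {
    tab <- table(gt[both], pred[both])
    inter[rownames(tab), colnames(tab)] <- tab
  }
  list(gids = gids, pids = pids, inter = inter,
       garea = tabulate(gt[gt > 0], nbins = max(gt, 1))[gids],
       parea = tabulate(pred[pred > 0], nbins = max(pred, 1))[pids])
}

#' Mean IoU of a predicted mask against ground truth
#'
#' For every ground-truth cell, the IoU with the prediction of maximal pixel
#' overlap (without uniqueness -- two ground-truth cells may share a best
#' prediction); undetected cells score 0.  The average runs over the
#' ground-truth cell count.
#'
#' @param gt_cells,pred_cells integer label masks of the same shape.
#' @return mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(gt_cells, pred_cells) {
  ot <- overlap_table(gt_cells, pred_cells)
  if (!length(ot$gids)) stop("empty ground truth", call. = FALSE)
  ious <- numeric(length(ot$gids))
  for (i in seq_along(ot$gids)) {
    ov <- ot$inter[i, ]
    if (!length(ov) || max(ov) == 0) next
    j <- which.max(ov)
    ious[i] <- ov[j] / (ot$garea[i] + ot$parea[j] - ov[j])
  }
  mean(ious)
}

#' Object-level precision/recall/F1 at an IoU threshold
#'
#' Candidate (gt, pred) pairs with IoU at least `tau` are matched greedily
#' in descending IoU, one-to-one.  Matched pairs are true positives,
#' unmatched predictions false positives (over-detection), unmatched
#' ground-truth cells false negatives (missed cells).  The conventional
#' reporting threshold is `tau = 0.7`.  `0/0` ratios are defined as 0.
#'
#' @param gt_cells,pred_cells integer label masks of the same shape.
#' @param tau IoU threshold in `(0, 1]`.
#' @return `list(precision, recall, f1, match)` where `match` holds the
#'   matched pairs (`gt_id`, `pred_id`, `iou`), the unmatched ids and `tau`.
#' @export
f1_at_threshold <- function(gt_cells, pred_cells, tau = 0.7) {
  stopifnot(tau > 0, tau <= 1)
  ot <- overlap_table(gt_cells, pred_cells)
  cand <- NULL
  if (length(ot$gids) && length(ot$pids)) {
    ious <- ot$inter / (outer(ot$garea, ot$parea, `+`) - ot$inter)
    hit <- which(ious >= tau, arr.ind = TRUE)
    if (nrow(hit))
      cand <- data.frame(gi = hit[, 1], pj = hit[, 2],
                         iou = ious[hit])[order(-ious[hit]), , drop = FALSE]
  }
  used_g <- logical(length(ot$gids)); used_p <- logical(length(ot$pids))
  pairs <- list()
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      gi <- cand$gi[r]; pj <- cand$pj[r]
      if (!used_g[gi] && !used_p[pj]) {
        used_g[gi] <- TRUE; used_p[pj] <- TRUE
        pairs[[length(pairs) + 1]] <-
          data.frame(gt_id = ot$gids[gi], pred_id = ot$pids[pj],
                     iou = cand$iou[r])
      }
    }
  }
  tp <- sum(used_g); fp <- sum(!used_p); fn <- sum(!used_g)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec  <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1   <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       match = list(pairs = if (length(pairs)) do.call(rbind, pairs)
                            else data.frame(gt_id = integer(0),
                                            pred_id = integer(0),
                                            iou = numeric(0)),
                    unmatched_gt = ot$gids[!used_g],
                    unmatched_pred = ot$pids[!used_p],
                    tau = tau))
}

#' Confusion matrix and per-class precision/recall/F1
#'
#' Rows are the true (manual) class, columns the predicted class.  Cells
#' carrying the unannotated sentinel (`NA` or 0) in the truth are excluded
#' before counting.  Per-class precision, recall and F1 come from the matrix
#' margins, with `0/0` defined as 0.
#'
#' @param true_classes,pred_classes equal-length integer class vectors
#'   (1-based; truth may contain `NA`/0 sentinels).
#' @param K number of classes.
#' @param class_names optional labels for the output.
#' @return `list(confusion, metrics)`: a `K x K` count matrix and a data
#'   frame of per-class precision/recall/F1.
#' @export
confusion_and_prf <- function(true_classes, pred_classes, K = 4L,
                              class_names = NULL) {
  if (length(true_classes) != length(pred_classes))
    stop("class vectors differ in length", call. = FALSE)
  keep <- !is.na(true_classes) & true_classes != 0
  tc <- true_classes[keep]; pc <- pred_classes[keep]
  cm <- matrix(0L, K, K)
  for (i in seq_along(tc)) cm[tc[i], pc[i]] <- cm[tc[i], pc[i]] + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    prec[k] <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec[k]  <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1[k]   <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(confusion = cm,
       metrics = data.frame(class = class_names, precision = prec,
                            recall = rec, f1 = f1))
}

#' Per-item KL divergence between paired proportion lists
#'
#' The cross-validation metric: for each held-out image,
#' `D_KL(true || pred)` with the classifier module's eps smoothing; smaller
#' means the inferred proportions approximate the truth more closely.
#'
#' @param true_props,pred_props lists (or matrices, row-wise) of
#'   proportion vectors, paired by position.
#' @param eps KL smoothing constant.
#' @return `list(per_item, mean)`.
#' @export
kl_eval <- function(true_props, pred_props, eps = 1e-8) {
  tl <- if (is.matrix(true_props)) asplit(true_props, 1) else true_props
  pl <- if (is.matrix(pred_props)) asplit(pred_props, 1) else pred_props
  if (length(tl) != length(pl))
    stop("proportion lists differ in length", call. = FALSE)
  per <- mapply(function(p, q) proportion_loss(p, q, eps = eps), tl, pl)
  list(per_item = as.numeric(per), mean = mean(per))
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum U with midrank ties; the two-sided p-value uses the normal
#' approximation with tie correction and continuity correction
#' (delegated to [stats::wilcox.test()], whose W statistic for `x` vs `y`
#' is exactly U).
#'
#' @param x,y numeric samples, each nonempty.
#' @return `list(U, p_value)`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Cliff's delta effect size with confidence interval
#'
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (n m)`, in `[-1, 1]`.  The
#' confidence interval uses Cliff's consistent variance estimator with
#' normal quantiles, truncated to `[-1, 1]`.  Conventional interpretation
#' bands (|delta| >= 0.330 medium, >= 0.474 large, matching Cohen's d of
#' 0.5 and 0.8) are attached for reporting.
#'
#' @param x,y numeric samples, each nonempty.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `effect_size`: `list(delta, ci_low, ci_high,
#'   n, m, conf_level, bands)`.
#' @export
cliffs_delta <- function(x, y, conf_level = 0.95) {
  n <- length(x); m <- length(y)
  if (!n || !m) stop("empty sample", call. = FALSE)
  dij <- sign(outer(x, y, `-`))
  delta <- mean(dij)
  di <- rowMeans(dij); dj <- colMeans(dij)
  if (n > 1 && m > 1) {
    s2 <- (m^2 * sum((di - delta)^2) + n^2 * sum((dj - delta)^2) -
             sum((dij - delta)^2)) / (n * m * (n - 1) * (m - 1))
    s2 <- max(s2, 0)
  } else s2 <- 1 / (n * m)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- max(-1, min(delta, delta - z * sqrt(s2)))
  hi <- min(1, max(delta, delta + z * sqrt(s2)))
  structure(list(delta = delta, ci_low = lo, ci_high = hi, n = n, m = m,
                 conf_level = conf_level,
                 bands = c(medium = 0.330, large = 0.474)),
            class = "effect_size")
}
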