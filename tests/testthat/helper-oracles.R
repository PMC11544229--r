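# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / enumeration so it cannot
# share a code path with the package implementation it checks.

# random label mask: up to n_obj rectangles stamped into an h x w matrix,
# later rectangles overwriting earlier ones (labels partition foreground)
random_label_mask <- function(h, w, n_obj, seed) {
  withr::with_seed(seed, {
    m <- matrix(0L, h, w)
    for (id in seq_len(n_obj)) {
      rh <- sample(2:max(2, h %/% 3), 1)
      rw <- sample(2:max(2, w %/% 3), 1)
      r0 <- sample(seq_len(h - rh + 1), 1)
      c0 <- sample(seq_len(w - rw + 1), 1)
      m[r0:(r0 + rh - 1), c0:(c0 + rw - 1)] <- id
    }
    # renumber to drop fully overwritten ids
    ids <- sort(unique(m[m > 0]))
    out <- matrix(0L, h, w)
    for (i in seq_along(ids)) out[m == ids[i]] <- i
    out
  })
}

# plain per-pair IoU by pixel enumeration
oracle_iou <- function(mask_a, mask_b, ida, idb) {
  a <- which(mask_a == ida); b <- which(mask_b == idb)
  length(intersect(a, b)) / length(union(a, b))
}

# mean IoU oracle: per gt label, find the prediction with the largest
# pixel intersection (0 if none), take its IoU, average over gt labels
oracle_mean_iou <- function(gt, pred) {
  gids <- sort(unique(gt[gt > 0]))
  pids <- sort(unique(pred[pred > 0]))
  vals <- vapply(gids, function(g) {
    gpix <- which(gt == g)
    ov <- vapply(pids, function(p) length(intersect(gpix, which(pred == p))),
                 numeric(1))
    if (!length(ov) || max(ov) == 0) return(0)
    oracle_iou(gt, pred, g, pids[which.max(ov)])
  }, numeric(1))
  mean(vals)
}

# F1 oracle: maximum-cardinality one-to-one matching over all candidate
# pairs with IoU >= tau, found by exhaustive recursion (feasible for <= 5
# objects per side)
oracle_f1 <- function(gt, pred, tau) {
  gids <- sort(unique(gt[gt > 0]))
  pids <- sort(unique(pred[pred > 0]))
  iou_mat <- outer(seq_along(gids), seq_along(pids),
                   Vectorize(function(i, j) oracle_iou(gt, pred, gids[i], pids[j])))
  ok <- iou_mat >= tau
  best <- 0L
  recurse <- function(i, used_p, count) {
    if (i > length(gids)) { best <<- max(best, count); return() }
    recurse(i + 1L, used_p, count)        # leave gt i unmatched
    for (j in seq_along(pids)) {
      if (!used_p[j] && isTRUE(ok[i, j])) {
        used_p[j] <- TRUE
        recurse(i + 1L, used_p, count + 1L)
        used_p[j] <- FALSE
      }
    }
  }
  if (length(gids) && length(pids)) recurse(1L, logical(length(pids)), 0L)
  tp <- best; fp <- length(pids) - tp; fn <- length(gids) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec  <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1   <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, tp = tp)
}

# uniform random point on the K-simplex (exponential spacings)
random_simplex <- function(K) {
  e <- stats::rexp(K)
  e / sum(e)
}

# small random RGB raster
random_raster <- function(h, w, seed) {
  withr::with_seed(seed,
    array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)),
          dim = c(h, w, 3)))
}
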