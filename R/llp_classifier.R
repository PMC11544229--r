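#' Recovery-phase class scheme
#'
#' The four recovery phases of regenerating muscle and their display colours:
#' stable (red; intact or fully regenerated myofibers), early (blue; ghost
#' fibers and infiltrate), mid (yellow; proliferating myoblasts), late
#' (orange; fusing myotubes with central nuclei).  White is the no-detection
#' sentinel (class code 0).
#'
#' @param K number of classes, `>= 2`.
#' @param names ordered class labels.
#' @param colors `K x 3` RGB matrix, rows distinct.
#' @return an object of class `class_scheme`.
#' @export
class_scheme <- function(K = 4L,
                         names = c("stable", "early", "mid", "late"),
                         colors = rbind(c(255, 0, 0), c(0, 0, 255),
                                        c(255, 255, 0), c(255, 165, 0))) {
  K <- as.integer(K)
  stopifnot(K >= 2, length(names) == K, nrow(colors) == K)
  if (anyDuplicated(apply(colors, 1, paste, collapse = ",")))
    stop("class colors must be distinct", call. = FALSE)
  structure(list(K = K, names = names, colors = unname(as.matrix(colors)),
                 sentinel_color = c(255, 255, 255)),
            class = "class_scheme")
}

#' Initialise 3-layer perceptron parameters
#'
#' Architecture `D -> H1 -> D' -> K` with ReLU between the fully connected
#' layers and softmax on the output.  He-style initialisation
#' (`N(0, sqrt(2 / fan_in))`), seeded; biases start at zero.
#'
#' @param D input dimensionality.
#' @param K number of classes.
#' @param H1 first hidden width (default `D`: the first layer preserves
#'   dimension).
#' @param Dprime compression width of the second layer (default 256).
#' @param seed RNG seed.
#' @return an object of class `mlp_params`.
#' @export
mlp_init <- function(D, K, H1 = D, Dprime = 256L, seed = 1L) {
  stopifnot(D > 0, K >= 2, H1 > 0, Dprime > 0)
  withr::with_seed(as.integer(seed), {
    p <- list(
      W1 = matrix(stats::rnorm(D * H1, 0, sqrt(2 / D)), D, H1),
      b1 = numeric(H1),
      W2 = matrix(stats::rnorm(H1 * Dprime, 0, sqrt(2 / H1)), H1, Dprime),
      b2 = numeric(Dprime),
      W3 = matrix(stats::rnorm(Dprime * K, 0, sqrt(2 / Dprime)), Dprime, K),
      b3 = numeric(K))
  })
  structure(c(p, list(D = as.integer(D), H1 = as.integer(H1),
                      Dprime = as.integer(Dprime), K = as.integer(K))),
            class = "mlp_params")
}

#' Row-wise softmax with max-shift stabilisation
#' @keywords internal
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass of the classifier
#'
#' `linear -> ReLU -> linear -> ReLU -> linear -> softmax`; outputs lie in
#' the open probability simplex (entries positive, sum 1).
#'
#' @param params an [mlp_init()] object.
#' @param x a length-`D` feature vector or an `N x D` matrix.
#' @return for a vector input, a length-`K` confidence vector; for a matrix,
#'   an `N x K` confidence matrix.
#' @export
forward <- function(params, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else x
  if (ncol(X) != params$D)
    stop("feature dimension ", ncol(X), " does not match D = ", params$D,
         call. = FALSE)
  S <- mlp_apply(params, X)$S
  if (single) S[1, ] else S
}

#' Forward pass keeping intermediates (for backprop)
#' @keywords internal
mlp_apply <- function(params, X) {
  Z1 <- sweep(X %*% params$W1, 2, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% params$W2, 2, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% params$W3, 2, params$b3, `+`)
  list(X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, S = softmax_rows(Z3))
}

#' Predict the hard class of a feature vector
#'
#' Argmax of the forward confidences; exact ties break toward the lowest
#' class index.
#'
#' @inheritParams forward
#' @return integer class index in `1..K` (or a vector of them for matrix
#'   input).
#' @export
predict_class <- function(params, x) {
  S <- forward(params, x)
  if (is.null(dim(S))) which.max(S) else max.col(S, ties.method = "first")
}

#' Group same-day instances into bags
#'
#' Instances are shuffled within each day (seeded) and partitioned into
#' consecutive bags of exactly `N`; the trailing remainder of each day is
#' dropped, so the bag count is `sum_j floor(n_j / N)`.  No bag mixes days.
#'
#' @param day_labels vector of per-instance day labels.
#' @param N bag size, `>= 1`.
#' @param seed RNG seed for the within-day shuffles.
#' @return list of bags `list(day, idx)` with `idx` 1-based instance indices.
#' @export
make_bags <- function(day_labels, N, seed = 1L) {
  stopifnot(N >= 1)
  N <- as.integer(N)
  bags <- list()
  withr::with_seed(as.integer(seed), {
    for (d in unique(day_labels)) {
      idx <- which(day_labels == d)
      idx <- idx[sample.int(length(idx))]
      nb <- length(idx) %/% N
      for (b in seq_len(nb))
        bags[[length(bags) + 1L]] <-
          list(day = d, idx = idx[((b - 1L) * N + 1L):(b * N)])
    }
  })
  bags
}

#' Predicted class proportion of a bag
#'
#' The bag's predicted proportion is the arithmetic mean of the member
#' confidences, `p_hat_k = (1/|B|) sum_x F(x)_k`.
#'
#' @param params classifier parameters.
#' @param bag a bag from [make_bags()].
#' @param features `N x D` feature matrix the bag indexes into.
#' @return length-`K` proportion vector on the simplex.
#' @export
predicted_proportion <- function(params, bag, features) {
  if (!length(bag$idx)) stop("empty bag", call. = FALSE)
  colMeans(forward(params, features[bag$idx, , drop = FALSE]))
}

#' KL proportion loss
#'
#' `D_KL(p_true || p_hat') = sum_k p_k log(p_k / p'_k)` in natural log,
#' where `p_hat' = (p_hat + eps)` renormalised guards zero predictions and
#' terms with `p_k = 0` contribute 0.  Nonnegative; zero (up to the eps
#' smoothing) iff the two proportions coincide.
#'
#' @param p_true,p_hat length-`K` vectors on the simplex.
#' @param eps smoothing constant added to `p_hat` (default `1e-8`).
#' @return nonnegative scalar.
#' @export
proportion_loss <- function(p_true, p_hat, eps = 1e-8) {
  stopifnot(length(p_true) == length(p_hat), eps > 0)
  q <- (p_hat + eps) / sum(p_hat + eps)
  pos <- p_true > 0
  sum(p_true[pos] * log(p_true[pos] / q[pos]))
}

#' Sample pseudo-labels from a day's class proportion
#'
#' Each instance independently draws class `k` with probability `p_k`; the
#' draws are returned one-hot.  This is the label-generation step of the
#' pseudo-label baseline.
#'
#' @param p length-`K` proportion vector.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return an `n x K` one-hot matrix (0 rows when `n = 0`).
#' @export
pseudo_label_sample <- function(p, n, seed = 1L) {
  K <- length(p)
  Y <- matrix(0, nrow = n, ncol = K)
  if (n == 0) return(Y)
  ks <- withr::with_seed(as.integer(seed),
                         sample.int(K, n, replace = TRUE, prob = p))
  Y[cbind(seq_len(n), ks)] <- 1
  Y
}

#' Batch cross-entropy loss
#'
#' `-sum_k y_k log F(x)_k`, averaged over the batch.  (The standard
#' cross-entropy reading: the one-hot label weights the log-confidence, so a
#' confident correct prediction approaches loss 0 and uniform confidences
#' give `log K`.)
#'
#' @param confidences length-`K` vector or `N x K` matrix of strictly
#'   positive confidences.
#' @param y matching one-hot vector or matrix.
#' @return nonnegative scalar.
#' @export
cross_entropy_loss <- function(confidences, y) {
  C <- if (is.null(dim(confidences))) matrix(confidences, nrow = 1) else confidences
  Y <- if (is.null(dim(y))) matrix(y, nrow = 1) else y
  stopifnot(all(dim(C) == dim(Y)))
  -mean(rowSums(Y * log(C)))
}

#' Training configuration
#'
#' @param loss_mode `"llp"` (KL proportion loss over bags) or `"pseudo"`
#'   (cross-entropy over sampled pseudo-labels).
#' @param bag_size bag size `N` (default 64).
#' @param epochs full passes over the data (default 300).
#' @param step_size SGD step size (default 0.05; see the methods vignette for
#'   why plain SGD needs a larger step than momentum methods here).
#' @param seed master seed; every stochastic element (initialisation, bag
#'   shuffles, pseudo-label draws) derives from it.
#' @param eps KL smoothing constant.
#' @param H1,Dprime hidden widths passed to [mlp_init()]; `H1 = NULL` means
#'   "equal to D".
#' @param batch_bags bags averaged per SGD step in LLP mode (default 1).
#' @return an object of class `train_config`.
#' @export
train_config <- function(loss_mode = c("llp", "pseudo"), bag_size = 64L,
                         epochs = 300L, step_size = 0.05, seed = 1L,
                         eps = 1e-8, H1 = NULL, Dprime = 256L,
                         batch_bags = 1L) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(bag_size >= 1, epochs >= 0, step_size > 0, eps > 0)
  structure(list(loss_mode = loss_mode, bag_size = as.integer(bag_size),
                 epochs = as.integer(epochs), step_size = step_size,
                 seed = as.integer(seed), eps = eps, H1 = H1,
                 Dprime = as.integer(Dprime),
                 batch_bags = as.integer(batch_bags)),
            class = "train_config")
}

#' Train the recovery-phase classifier from day-level proportions
#'
#' Seeded mini-batch gradient descent.  In `"llp"` mode each step
#' backpropagates the mean KL proportion loss of a batch of bags (bags
#' reshuffled every epoch); the classifier never sees an instance label.  In
#' `"pseudo"` mode each instance draws a one-hot pseudo-label from its day's
#' proportion (fresh draws every epoch) and steps on batch cross-entropy.
#'
#' @param features `N x D` feature matrix.
#' @param day_labels length-`N` vector of day labels.
#' @param day_proportions a [day_proportion_table()] (or a numeric matrix
#'   with one row per day, rownames the day labels).
#' @param config a [train_config()].
#' @param init optional `mlp_params` to warm-start from (default: fresh
#'   He-initialised parameters seeded by the config).
#' @return an object of class `llp_classifier`: `list(params, trace, config)`
#'   where `trace` is the per-epoch mean loss.
#' @export
train_classifier <- function(features, day_labels, day_proportions,
                             config = train_config(), init = NULL) {
  P <- as_day_matrix(day_proportions)
  days <- as.character(day_labels)
  if (!all(unique(days) %in% rownames(P)))
    stop("day labels missing from the proportion table: ",
         paste(setdiff(unique(days), rownames(P)), collapse = ", "),
         call. = FALSE)
  D <- ncol(features); K <- ncol(P)
  H1 <- if (is.null(config$H1)) D else as.integer(config$H1)
  params <- if (is.null(init)) mlp_init(D, K, H1 = H1, Dprime = config$Dprime,
                                        seed = config$seed) else init
  trace <- numeric(config$epochs)
  if (config$epochs == 0)
    return(structure(list(params = params, trace = trace, config = config),
                     class = "llp_classifier"))
  lr <- config$step_size
  for (ep in seq_len(config$epochs)) {
    ep_seed <- (config$seed * 1000L + ep) %% .Machine$integer.max
    if (config$loss_mode == "llp") {
      bags <- make_bags(days, config$bag_size, seed = ep_seed)
      if (!length(bags))
        stop("no full bags: bag_size exceeds every day's instance count",
             call. = FALSE)
      losses <- numeric(length(bags))
      nb <- config$batch_bags
      starts <- seq(1, length(bags), by = nb)
      for (s in starts) {
        chunk <- bags[s:min(s + nb - 1, length(bags))]
        grad <- NULL
        for (ci in seq_along(chunk)) {
          bag <- chunk[[ci]]
          fb <- llp_bag_grad(params, features[bag$idx, , drop = FALSE],
                             P[bag$day, ], config$eps)
          losses[s + ci - 1] <- fb$loss
          grad <- if (is.null(grad)) fb$grad
                  else mapply(`+`, grad, fb$grad, SIMPLIFY = FALSE)
        }
        params <- sgd_step(params, grad, lr / length(chunk))
      }
      trace[ep] <- mean(losses)
    } else {
      # pseudo-label mode: fresh one-hot draws each epoch, minibatch CE
      order_seed <- (ep_seed + 1L) %% .Machine$integer.max
      Y <- matrix(0, nrow = nrow(features), ncol = K)
      for (d in unique(days)) {
        idx <- which(days == d)
        Y[idx, ] <- pseudo_label_sample(P[d, ], length(idx), seed = ep_seed)
      }
      ord <- withr::with_seed(order_seed, sample.int(nrow(features)))
      bs <- config$bag_size
      starts <- seq(1, length(ord), by = bs)
      losses <- numeric(length(starts))
      for (si in seq_along(starts)) {
        idx <- ord[starts[si]:min(starts[si] + bs - 1, length(ord))]
        fb <- ce_batch_grad(params, features[idx, , drop = FALSE],
                            Y[idx, , drop = FALSE])
        losses[si] <- fb$loss
        params <- sgd_step(params, fb$grad, lr)
      }
      trace[ep] <- mean(losses)
    }
  }
  structure(list(params = params, trace = trace, config = config),
            class = "llp_classifier")
}

#' Loss and gradient of one bag under the proportion loss
#' @keywords internal
llp_bag_grad <- function(params, X, p_true, eps) {
  f <- mlp_apply(params, X)
  N <- nrow(X); K <- length(p_true)
  p_hat <- colMeans(f$S)
  z <- sum(p_hat + eps)
  q <- (p_hat + eps) / z
  pos <- p_true > 0
  loss <- sum(p_true[pos] * log(p_true[pos] / q[pos]))
  # dL/dp_hat through the renormalised smoothing
  g_q <- ifelse(pos, -p_true / q, 0)
  g_phat <- (g_q - sum(g_q * q)) / z
  dS <- matrix(g_phat / N, nrow = N, ncol = K, byrow = TRUE)
  list(loss = loss, grad = mlp_backward(params, f, dS_to_dZ3(f$S, dS)))
}

#' Loss and gradient of a cross-entropy minibatch
#' @keywords internal
ce_batch_grad <- function(params, X, Y) {
  f <- mlp_apply(params, X)
  loss <- -mean(rowSums(Y * log(pmax(f$S, 1e-300))))
  dZ3 <- (f$S - Y) / nrow(X)
  list(loss = loss, grad = mlp_backward(params, f, dZ3))
}

#' Softmax backward: gradient w.r.t. logits from gradient w.r.t. outputs
#' @keywords internal
dS_to_dZ3 <- function(S, dS) {
  S * (dS - rowSums(dS * S))
}

#' Backpropagate through the two hidden layers
#' @keywords internal
mlp_backward <- function(params, f, dZ3) {
  dA2 <- dZ3 %*% t(params$W3)
  dZ2 <- dA2 * (f$Z2 > 0)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * (f$Z1 > 0)
  list(W1 = t(f$X) %*% dZ1, b1 = colSums(dZ1),
       W2 = t(f$A1) %*% dZ2, b2 = colSums(dZ2),
       W3 = t(f$A2) %*% dZ3, b3 = colSums(dZ3))
}

#' One SGD parameter update
#' @keywords internal
sgd_step <- function(params, grad, lr) {
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
    params[[nm]] <- params[[nm]] - lr * grad[[nm]]
  params
}

#' Serialise / restore a trained classifier
#'
#' Parameters and dimensions are written as portable JSON-of-arrays with the
#' training config echoed alongside, so a model file is self-describing.
#'
#' @param model an `llp_classifier` (or bare `mlp_params`).
#' @param path output JSON path.
#' @return `save_classifier`: `path` invisibly; `load_classifier`: the
#'   restored object.
#' @export
save_classifier <- function(model, path) {
  params <- if (inherits(model, "llp_classifier")) model$params else model
  obj <- list(
    dims = list(D = params$D, H1 = params$H1, Dprime = params$Dprime,
                K = params$K),
    weights = lapply(params[c("W1", "b1", "W2", "b2", "W3", "b3")], unclass),
    trace = if (inherits(model, "llp_classifier")) model$trace else NULL,
    config = if (inherits(model, "llp_classifier"))
      unclass(model$config) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dims
  params <- structure(list(
    W1 = matrix(unlist(obj$weights$W1), d$D, d$H1),
    b1 = as.numeric(obj$weights$b1),
    W2 = matrix(unlist(obj$weights$W2), d$H1, d$Dprime),
    b2 = as.numeric(obj$weights$b2),
    W3 = matrix(unlist(obj$weights$W3), d$Dprime, d$K),
    b3 = as.numeric(obj$weights$b3),
    D = d$D, H1 = d$H1, Dprime = d$Dprime, K = d$K), class = "mlp_params")
  cfg <- obj$config
  if (!is.null(cfg)) cfg <- structure(cfg, class = "train_config")
  structure(list(params = params,
                 trace = as.numeric(obj$trace), config = cfg),
            class = "llp_classifier")
}
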