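zero_params <- function(D = 4, K = 4) {
  p <- mlp_init(D, K, H1 = 3, Dprime = 2, seed = 1)
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) p[[nm]][] <- 0
  p
}

test_that("forward produces simplex confidences; zero weights give uniform", {
  p <- zero_params()
  expect_equal(forward(p, rep(1, 4)), rep(0.25, 4))

  p2 <- mlp_init(6, 4, seed = 3)
  X <- matrix(rnorm(30), 5, 6)
  S <- forward(p2, X)
  expect_true(all(S > 0))
  expect_equal(rowSums(S), rep(1, 5), tolerance = 1e-9)
  expect_error(forward(p2, rep(0, 5)), "does not match")
})

test_that("softmax matches the closed form on hand-set logits", {
  # 2-class net arranged so the logits are (ln 3, 0)
  p <- zero_params(D = 2, K = 4)
  p <- mlp_init(2, 2, H1 = 2, Dprime = 2, seed = 1)
  for (nm in c("W1", "b1", "W2", "b2", "W3")) p[[nm]][] <- 0
  p$b3 <- c(log(3), 0)
  expect_equal(forward(p, c(0, 0)), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("predict_class is argmax with ties toward the lowest index", {
  p <- mlp_init(3, 4, seed = 5)
  X <- matrix(rnorm(60), 20, 3)
  S <- forward(p, X)
  manual <- apply(S, 1, function(r) which(r == max(r))[1])
  expect_equal(predict_class(p, X), manual)

  pz <- zero_params(D = 3, K = 4)   # all-uniform: exact 4-way tie
  expect_equal(predict_class(pz, c(1, 2, 3)), 1L)
})

test_that("make_bags partitions within days, drops remainders, is seeded", {
  days <- rep("3", 10)
  bags <- make_bags(days, 3, seed = 1)
  expect_length(bags, 3)
  expect_true(all(lengths(lapply(bags, `[[`, "idx")) == 3))
  expect_length(unique(unlist(lapply(bags, `[[`, "idx"))), 9)

  b1 <- make_bags(rep(c("a", "b"), each = 7), 2, seed = 9)
  expect_true(all(vapply(b1, function(b)
    length(unique(rep(c("a", "b"), each = 7)[b$idx])) == 1, logical(1))))
  expect_length(b1, 6)

  expect_length(make_bags(days, 1, seed = 2), 10)
  expect_identical(make_bags(days, 3, seed = 4), make_bags(days, 3, seed = 4))
})

test_that("predicted_proportion equals the brute-force confidence mean", {
  p <- mlp_init(5, 4, seed = 2)
  X <- matrix(rnorm(100), 20, 5)
  bag <- list(day = "0", idx = c(3, 7, 11, 18))
  expect_equal(predicted_proportion(p, bag, X),
               colMeans(forward(p, X)[bag$idx, ]))
  expect_error(predicted_proportion(p, list(day = "0", idx = integer(0)), X),
               "empty bag")
})

test_that("proportion loss: identity, ln 2 oracle, asymmetry", {
  p <- c(0.3, 0.3, 0.2, 0.2)
  expect_lt(proportion_loss(p, p), 1e-6)
  expect_equal(proportion_loss(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0), eps = 1e-12),
               log(2), tolerance = 1e-9)
  a <- c(0.9, 0.1, 0, 0); b <- c(0.5, 0.5, 0, 0)
  expect_false(isTRUE(all.equal(proportion_loss(a, b),
                                proportion_loss(b, a))))
})

test_that("proportion loss is nonnegative, zero iff equal, on random pairs", {
  withr::with_seed(42, {
    for (i in 1:200) {
      p <- random_simplex(4); q <- random_simplex(4)
      expect_gte(proportion_loss(p, q), 0)
    }
    for (i in 1:50) {
      p <- random_simplex(4)
      expect_lt(proportion_loss(p, p), 1e-6)
    }
  })
})

test_that("pseudo-label sampling matches the target distribution", {
  Y <- pseudo_label_sample(c(1, 0, 0, 0), 50, seed = 1)
  expect_true(all(Y[, 1] == 1))
  expect_true(all(Y[, -1] == 0))

  expect_equal(nrow(pseudo_label_sample(rep(0.25, 4), 0, seed = 1)), 0)

  n <- 10000
  Y2 <- pseudo_label_sample(rep(0.25, 4), n, seed = 7)
  freq <- colMeans(Y2)
  tol <- 4 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < tol))
})

test_that("cross-entropy: perfect limit, uniform value, monotonicity", {
  y <- c(1, 0, 0, 0)
  expect_lt(cross_entropy_loss(c(1 - 3e-12, 1e-12, 1e-12, 1e-12), y), 1e-10)
  expect_equal(cross_entropy_loss(rep(0.25, 4), y), log(4))
  expect_lt(cross_entropy_loss(c(0.75, 0.25 / 3, 0.25 / 3, 0.25 / 3), y),
            cross_entropy_loss(c(0.25, 0.25, 0.25, 0.25), y))
})

test_that("training is seeded-deterministic and 0 epochs is a no-op", {
  ds <- generate_feature_dataset(
    feature_sim_config(D = 8, n_per_day = 60, seed = 1))
  cfg0 <- train_config("llp", bag_size = 10, epochs = 0, seed = 3)
  f0 <- train_classifier(ds$features, ds$day, ctx_schedule(), cfg0)
  expect_identical(f0$params, mlp_init(8, 4, H1 = 8, Dprime = 256, seed = 3))
  expect_length(f0$trace, 0)

  cfg <- train_config("llp", bag_size = 10, epochs = 3, seed = 3)
  fa <- train_classifier(ds$features, ds$day, ctx_schedule(), cfg)
  fb <- train_classifier(ds$features, ds$day, ctx_schedule(), cfg)
  expect_identical(fa$trace, fb$trace)
  expect_identical(fa$params, fb$params)

  expect_error(train_classifier(ds$features, rep("99", nrow(ds$features)),
                                ctx_schedule(), cfg), "missing")
})

test_that("pseudo-label training runs and reduces its loss", {
  ds <- generate_feature_dataset(
    feature_sim_config(D = 8, separation = 4, n_per_day = 80, seed = 2))
  fit <- train_classifier(ds$features, ds$day, ctx_schedule(),
                          train_config("pseudo", 16, epochs = 15, seed = 1))
  expect_lt(tail(fit$trace, 1), fit$trace[1])
  expect_true(all(fit$trace > 0))
})

test_that("proportion of a union of equal bags is the mean of proportions", {
  p <- mlp_init(5, 4, seed = 8)
  X <- matrix(rnorm(200), 40, 5)
  b1 <- list(day = "0", idx = 1:10); b2 <- list(day = "0", idx = 11:20)
  bu <- list(day = "0", idx = 1:20)
  expect_equal(predicted_proportion(p, bu, X),
               (predicted_proportion(p, b1, X) +
                predicted_proportion(p, b2, X)) / 2)
})

test_that("classifier serialisation round-trips", {
  ds <- generate_feature_dataset(
    feature_sim_config(D = 8, n_per_day = 40, seed = 5))
  fit <- train_classifier(ds$features, ds$day, ctx_schedule(),
                          train_config("llp", 8, epochs = 2, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(fit, f)
  back <- load_classifier(f)
  expect_equal(back$params$W2, fit$params$W2, tolerance = 1e-12)
  expect_equal(forward(back$params, ds$features[1, ]),
               forward(fit$params, ds$features[1, ]), tolerance = 1e-12)
})
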