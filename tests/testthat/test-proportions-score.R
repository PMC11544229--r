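paint <- function(h, w, color) new_raster(h, w, fill = color)

test_that("annotation proportions count palette pixels and pool by day", {
  scheme <- class_scheme()
  red <- scheme$colors[1, ]; blue <- scheme$colors[2, ]

  tab <- proportions_from_annotations(
    list(list(raster = paint(10, 10, red), day = 0)), scheme)
  expect_equal(unname(unclass(tab)["0", ]), c(1, 0, 0, 0))

  # four equal colour quadrants
  q <- new_raster(20, 20)
  for (k in 1:4) {
    ys <- if (k <= 2) 1:10 else 11:20
    xs <- if (k %% 2 == 1) 1:10 else 11:20
    for (ch in 1:3) q[ys, xs, ch] <- scheme$colors[k, ch]
  }
  tq <- proportions_from_annotations(list(list(raster = q, day = 5)), scheme)
  expect_equal(unname(unclass(tq)["5", ]), rep(0.25, 4))

  # two slides of one day pool pixel counts: 300R+100B and 100R+300B
  a1 <- paint(20, 20, red);  a1[1:5, , ] <- rep(blue, each = 100)
  a2 <- paint(20, 20, blue); a2[1:5, , ] <- rep(red, each = 100)
  tp <- proportions_from_annotations(
    list(list(raster = a1, day = 3), list(raster = a2, day = 3)), scheme)
  expect_equal(unname(unclass(tp)["3", ]), c(0.5, 0.5, 0, 0))

  # splitting a raster into pieces changes nothing (pooling property)
  whole <- proportions_from_annotations(
    list(list(raster = a1, day = 3)), scheme)
  pieces <- proportions_from_annotations(
    list(list(raster = a1[1:10, , , drop = FALSE], day = 3),
         list(raster = a1[11:20, , , drop = FALSE], day = 3)), scheme)
  expect_equal(unclass(whole)["3", ], unclass(pieces)["3", ])

  expect_error(proportions_from_annotations(
    list(list(raster = paint(5, 5, c(255, 255, 255)), day = 9)), scheme),
    "zero annotated")
})

test_that("classmap proportions respect the mask", {
  cm <- matrix(1L, 10, 10)
  expect_equal(classmap_proportions(cm), c(1, 0, 0, 0))

  cm2 <- matrix(0L, 10, 10); cm2[1:5, ] <- 1L; cm2[6:10, ] <- 4L
  expect_equal(classmap_proportions(cm2), c(0.5, 0, 0, 0.5))

  # pixels outside the mask are never counted
  msk <- matrix(FALSE, 10, 10); msk[1:5, ] <- TRUE
  expect_equal(classmap_proportions(cm2, msk), c(1, 0, 0, 0))

  expect_error(classmap_proportions(matrix(0L, 4, 4)), "empty cell mask")
})

test_that("sigmoid hits its inflection and asymptotes", {
  m <- sigmoid_model(a = 0.65, d = 6)
  expect_equal(sigmoid(6, m), 0.5)
  expect_equal(sigmoid(0, m), 1 / (1 + exp(3.9)), tolerance = 1e-12)
  expect_equal(sigmoid(1e6, m), 1)
  expect_equal(sigmoid(-1e6, m), 0)
  expect_true(all(diff(sigmoid(seq(-20, 20, by = 0.5), m)) > 0))
  expect_error(sigmoid_model(a = -1), "a > 0")
})

test_that("identity design recovers the sigmoid targets exactly", {
  days <- c(0, 3, 7, 14)
  w <- fit_weights(diag(4), days, sigmoid_model())
  expect_equal(w$omega, sigmoid(days, sigmoid_model()), tolerance = 1e-10)
  expect_lt(w$fit_residual, 1e-10)
})

test_that("rank-deficient designs give the minimum-norm solution", {
  P <- matrix(rep(c(1, 0, 0, 0), 4), 4, byrow = TRUE)
  expect_warning(w <- fit_weights(P, rep(6, 4), sigmoid_model()),
                 "rank-deficient")
  expect_equal(w$omega, c(0.5, 0, 0, 0), tolerance = 1e-10)
})

test_that("exact-fit weights are recovered on full-rank designs", {
  withr::with_seed(31, {
    P <- t(vapply(1:6, function(i) random_simplex(4), numeric(4)))
    omega_star <- c(0.1, 0.3, 0.6, 0.9)
    targets <- as.numeric(P %*% omega_star)
    # choose days whose sigmoid values equal the targets
    m <- sigmoid_model()
    days <- m$d - log(1 / targets - 1) / m$a
    w <- fit_weights(P, days, m)
    expect_equal(w$omega, omega_star, tolerance = 1e-8)
  })
})

test_that("recovery score is the clipped-weight dot product", {
  w <- structure(list(omega = c(1, 0, 0.2, 0.6)), class = "recovery_weights")
  expect_equal(recovery_score(c(0.5, 0.25, 0.25, 0), w), 0.55)
  for (k in 1:4) {
    p <- rep(0, 4); p[k] <- 1
    expect_equal(recovery_score(p, w), w$omega[k])
  }
  wc <- structure(list(omega = rep(0.4, 4)), class = "recovery_weights")
  expect_equal(recovery_score(random_simplex(4), wc), 0.4)
})

test_that("score is monotone when mass moves to a higher-weight class", {
  w <- c(0.1, 0.2, 0.6, 0.9)
  p <- c(0.4, 0.3, 0.2, 0.1)
  for (shift in c(0.05, 0.1)) {
    p2 <- p; p2[1] <- p[1] - shift; p2[4] <- p[4] + shift
    expect_gt(recovery_score(p2, w), recovery_score(p, w))
  }
})

test_that("day proportion table validates simplex rows", {
  expect_error(day_proportion_table(c(0, 3), rbind(c(0.5, 0.5, 0, 0),
                                                   c(0.7, 0.7, 0, 0))),
               "sum to 1")
  expect_error(day_proportion_table(c(0, 0), matrix(0.25, 2, 4)))
})
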