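test_that("iou handles identity, disjoint and partial overlap", {
  a <- matrix(FALSE, 5, 5); a[2:3, 2:3] <- TRUE
  expect_equal(iou(a, a), 1)
  b <- matrix(FALSE, 5, 5); b[5, 5] <- TRUE
  expect_equal(iou(a, b), 0)
  shifted <- matrix(FALSE, 5, 5); shifted[2:3, 3:4] <- TRUE
  expect_equal(iou(a, shifted), 2 / 6)
  expect_error(iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "undefined")
})

test_that("mean_iou: perfect, empty-prediction, and oracle equivalence", {
  gt <- random_label_mask(15, 15, 3, seed = 1)
  expect_equal(mean_iou(gt, gt), 1)
  expect_equal(mean_iou(gt, matrix(0L, 15, 15)), 0)
  expect_error(mean_iou(matrix(0L, 5, 5), gt[1:5, 1:5]), "empty ground truth")

  for (seed in 1:20) {
    gt <- random_label_mask(20, 20, sample(1:5, 1), seed = seed)
    pr <- random_label_mask(20, 20, sample(1:5, 1), seed = seed + 1000)
    if (max(gt) == 0) next
    expect_equal(mean_iou(gt, pr), oracle_mean_iou(gt, pr))
  }
})

test_that("f1_at_threshold matches the exhaustive matching oracle", {
  gt <- random_label_mask(15, 15, 3, seed = 2)
  perfect <- f1_at_threshold(gt, gt, 0.7)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  none <- f1_at_threshold(gt, matrix(0L, 15, 15), 0.7)
  expect_equal(none$recall, 0)
  expect_equal(none$f1, 0)

  for (seed in 1:20) {
    gt <- random_label_mask(18, 18, sample(1:5, 1), seed = seed + 50)
    pr <- random_label_mask(18, 18, sample(1:5, 1), seed = seed + 2000)
    got <- f1_at_threshold(gt, pr, 0.7)
    want <- oracle_f1(gt, pr, 0.7)
    expect_equal(got$f1, want$f1)
    expect_equal(nrow(got$match$pairs), want$tp)
  }
})

test_that("f1 is monotone non-increasing in the IoU threshold", {
  gt <- random_label_mask(25, 25, 5, seed = 11)
  pr <- random_label_mask(25, 25, 5, seed = 99)
  f1s <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9),
                function(t) f1_at_threshold(gt, pr, t)$f1, numeric(1))
  expect_true(all(diff(f1s) <= 1e-12))
})

test_that("confusion matrix margins give precision and recall", {
  res <- confusion_and_prf(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(diag(res$confusion)), rep(1L, 4))
  expect_true(all(res$metrics$f1 == 1))

  # everything predicted class 1 under uniform truth
  res2 <- confusion_and_prf(rep(1:4, each = 5), rep(1, 20))
  expect_equal(res2$metrics$recall[1], 1)
  expect_equal(res2$metrics$precision[1], 0.25)
  expect_equal(res2$metrics$f1[2:4], rep(0, 3))

  # sentinel-labelled cells change no counts
  res3 <- confusion_and_prf(c(rep(1:4, each = 5), 0, NA),
                            c(rep(1, 20), 3, 4))
  expect_identical(res3$confusion, res2$confusion)

  expect_error(confusion_and_prf(1:3, 1:4), "length")

  withr::with_seed(8, {
    tc <- sample(1:4, 60, replace = TRUE)
    pc <- sample(1:4, 60, replace = TRUE)
    r <- confusion_and_prf(tc, pc)
    expect_equal(r$metrics$recall,
                 unname(diag(r$confusion) / rowSums(r$confusion)))
  })
})

test_that("kl_eval reports per-item divergences and their mean", {
  same <- list(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  r <- kl_eval(same, same)
  expect_true(all(r$per_item < 1e-6))

  r2 <- kl_eval(list(c(1, 0, 0, 0)), list(c(0.5, 0.5, 0, 0)), eps = 1e-12)
  expect_equal(r2$per_item, log(2), tolerance = 1e-9)

  withr::with_seed(3, {
    tp <- lapply(1:6, function(i) random_simplex(4))
    pp <- lapply(1:6, function(i) random_simplex(4))
  })
  r3 <- kl_eval(tp, pp)
  expect_equal(r3$mean, mean(r3$per_item))
  expect_error(kl_eval(tp, pp[1:3]), "length")
})

test_that("Mann-Whitney U behaves at the null and under separation", {
  x <- c(1, 2, 3, 4, 5)
  r <- mann_whitney_u(x, x)
  expect_equal(r$U, length(x)^2 / 2)
  expect_gt(r$p_value, 0.9)

  withr::with_seed(5, {
    lo <- runif(20, 0, 1); hi <- runif(20, 2, 3)
  })
  expect_lt(mann_whitney_u(hi, lo)$p_value, 0.001)

  # complementarity U_x + U_y = n m
  withr::with_seed(6, {
    a <- rnorm(13); b <- rnorm(9)
  })
  expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U, 13 * 9)

  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Cliff's delta matches pair enumeration and is antisymmetric", {
  r <- cliffs_delta(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$delta, -5 / 9)
  expect_lte(r$ci_low, r$delta)
  expect_gte(r$ci_high, r$delta)

  expect_equal(cliffs_delta(10:12, 1:3)$delta, 1)
  expect_equal(cliffs_delta(1:5, 1:5)$delta, 0)

  withr::with_seed(17, {
    for (i in 1:50) {
      x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
      rx <- cliffs_delta(x, y); ry <- cliffs_delta(y, x)
      expect_equal(rx$delta, -ry$delta)
      expect_true(rx$delta >= -1 && rx$delta <= 1)
      expect_true(rx$ci_low <= rx$delta && rx$delta <= rx$ci_high)
    }
  })
})
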