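test_that("single-class phantoms are pure and internally consistent", {
  ph <- generate_tissue_phantom(
    phantom_config(size = c(256, 256), proportions = c(1, 0, 0, 0), seed = 2))
  expect_true(all(ph$gt_class == 1))
  expect_equal(ph$realized_proportions, c(1, 0, 0, 0))

  # realized proportions recomputed independently from mask + classes
  counts <- vapply(1:4, function(k) {
    ids <- which(ph$gt_class == k)
    sum(ph$gt_mask %in% ids)
  }, numeric(1))
  expect_equal(ph$realized_proportions, counts / sum(counts))
})

test_that("phantoms are seeded-deterministic", {
  cfg <- phantom_config(size = c(192, 192),
                        proportions = c(0.4, 0.2, 0.2, 0.2), seed = 7)
  a <- generate_tissue_phantom(cfg)
  b <- generate_tissue_phantom(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_mask, b$gt_mask)
  expect_identical(a$rough_annotation, b$rough_annotation)
})

test_that("mixed-class phantoms hit target proportions within tolerance", {
  ph <- generate_tissue_phantom(
    phantom_config(size = c(1024, 1024), proportions = rep(0.25, 4),
                   seed = 5))
  expect_true(all(abs(ph$realized_proportions - 0.25) <= 0.05))
  # every cell has a class; annotation colours match classes
  expect_equal(max(ph$gt_mask), length(ph$gt_class))
  scheme <- class_scheme()
  for (k in 1:4) {
    ids <- which(ph$gt_class == k)
    if (!length(ids)) next
    sel <- ph$gt_mask %in% ids
    expect_true(all(ph$rough_annotation[, , 1][sel] == scheme$colors[k, 1]))
  }
})

test_that("gaussian features separate at zero noise and concentrate by day", {
  cfg <- feature_sim_config(D = 8, K = 4, separation = 6, sigma = 1e-9,
                            n_per_day = 50, seed = 3)
  ds <- generate_feature_dataset(cfg)
  near <- apply(ds$features, 1, function(x)
    which.min(colSums((t(cfg$means) - x)^2)))
  expect_equal(unname(near), ds$class)

  cfg2 <- feature_sim_config(D = 8, n_per_day = 4000, seed = 4)
  ds2 <- generate_feature_dataset(cfg2)
  P <- unclass(ctx_schedule())
  for (d in rownames(P)) {
    freq <- tabulate(ds2$class[ds2$day == d], 4) / 4000
    tol <- 4 * sqrt(pmax(P[d, ] * (1 - P[d, ]), 1e-4) / 4000)
    expect_true(all(abs(freq - P[d, ]) <= tol))
  }
})

test_that("augmentation yields exactly 16 variants per input", {
  imgs <- list(random_raster(32, 32, seed = 1), random_raster(32, 32, seed = 2))
  out <- augment_geometric_photometric(imgs, seed = 1)
  expect_length(out, 32)

  # four 90-degree rotations compose to the identity
  r <- imgs[[1]]
  for (i in 1:4) r <- myophase:::rot90_raster(r)
  expect_identical(r, imgs[[1]])

  # with jitter probability 0 the photometric copies equal their variants
  out0 <- augment_geometric_photometric(imgs[1], seed = 1, jitter_p = 0)
  expect_identical(out0[1:8], out0[9:16])
  expect_identical(out0[[1]], imgs[[1]])

  expect_error(augment_geometric_photometric(
    list(random_raster(16, 32, seed = 3))), "square")
})

test_that("mask-image pairs stay aligned under all geometric variants", {
  img <- new_raster(16, 16)
  img[3, 5, ] <- c(9, 9, 9)                   # one marked pixel
  msk <- matrix(0L, 16, 16); msk[3, 5] <- 1L
  out <- augment_geometric_photometric(list(img), seed = 2, masks = list(msk))
  expect_length(out$images, 16)
  expect_length(out$masks, 16)
  for (v in 1:8) {
    im <- out$images[[v]]; mk <- out$masks[[v]]
    expect_equal(sum(mk), 1)
    expect_equal(which(im[, , 1] == 9), which(mk == 1L))
  }
})

test_that("random crops stay in bounds and are seeded", {
  tile <- random_raster(256, 256, seed = 6)
  crops <- random_crops(tile, n = 100, size = 64, seed = 1)
  expect_length(crops, 100)
  pos <- attr(crops, "positions")
  expect_true(all(pos >= 0) && all(pos <= 256 - 64))
  expect_true(all(vapply(crops, function(cr)
    all(dim(cr) == c(64, 64, 3)), logical(1))))

  expect_length(random_crops(tile, n = 0, size = 64, seed = 1), 0)
  expect_identical(attr(random_crops(tile, 5, 64, seed = 9), "positions"),
                   attr(random_crops(tile, 5, 64, seed = 9), "positions"))
  expect_error(random_crops(tile, 1, 300, seed = 1), "exceeds")
})
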